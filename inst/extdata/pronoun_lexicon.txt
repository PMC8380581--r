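# Open pronoun-category lexicon: one category per line, "category: words".
# Six disjoint categories; the total-pronoun fraction is their sum.
first_singular: i me my mine myself im i'm i've i'd i'll
first_plural: we us our ours ourselves we're we've we'll lets let's
second: you your yours yourself yourselves you're you've you'll u ur
third_singular: she he her him his hers herself himself she's he's she'd he'd she'll he'll
third_plural: they them their theirs themselves they're they've they'll
impersonal: it its it's this that these those something anything nothing everything somebody anybody nobody everybody someone anyone everyone what which who whom whose whatever whoever stuff thing things
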