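test_that("the four rewrite rules apply and compose", {
  expect_identical(normalize_text("#depression"), "hashtag depression")
  expect_identical(normalize_text(""), "")
  expect_identical(normalize_text("@bob scored 42 http://x.co"),
                   "user scored number url")
  expect_identical(normalize_text("@a_1 says 3.14 and 1,000 www.x.org #ok"),
                   "user says number and number url hashtag ok")
  # digits inside words or URLs are untouched by the numeral rule
  expect_identical(normalize_text("room b12"), "room b12")
})

test_that("normalisation is idempotent on generated raw text", {
  co <- tiny_corpus(n_pos = 20, n_ctl = 20, posts = 10, seed = 99)
  texts <- unlist(lapply(co$users, function(u) u$posts$text))
  once <- normalize_text(texts)
  expect_identical(normalize_text(once), once)
})

test_that("user filtering uses strict removal bounds", {
  co <- manual_corpus(list(
    manual_user("a", 0, rep("x", 99)),                       # too few posts
    manual_user("b", 0, rep("x", 100)),                      # boundary: kept
    manual_user("c", 1, rep("x", 120),
                english = c(rep(TRUE, 95), rep(FALSE, 25))), # 79% English
    manual_user("d", 1, rep("x", 120),
                english = c(rep(TRUE, 96), rep(FALSE, 24))), # exactly 80%
    manual_user("e", 1, rep("x", 150))))
  kept <- vapply(filter_users(co)$users, `[[`, character(1), "user_id")
  expect_identical(kept, c("b", "d", "e"))

  # brute-force oracle over a random 10-user corpus
  set.seed(1)
  users <- lapply(1:10, function(i) {
    n <- sample(80:130, 1)
    manual_user(paste0("u", i), i %% 2, rep("x", n),
                english = runif(n) < 0.85)
  })
  co2 <- manual_corpus(users)
  manual_keep <- vapply(users, function(u)
    nrow(u$posts) >= 100 && mean(u$posts$is_english) >= 0.8, logical(1))
  expect_identical(vapply(filter_users(co2)$users, `[[`, character(1),
                          "user_id"),
                   vapply(users[manual_keep], `[[`, character(1), "user_id"))

  # pluggable language predicate overrides the stored flags
  co3 <- manual_corpus(list(manual_user("z", 0, rep("bonjour", 100))))
  expect_length(filter_users(co3, is_english = function(t)
    !grepl("bonjour", t))$users, 0L)
})

test_that("tokenisation lowercases and truncates to the budget", {
  long <- paste(rep("w", 60), collapse = " ")
  expect_length(tokenize(long), 55L)
  expect_identical(tokenize(""), character())
  expect_identical(tokenize("Hashtag Depression"),
                   c("hashtag", "depression"))
  expect_length(tokenize(long, max_tokens = 10), 10L)
})

test_that("vocabulary is frequency-ranked with reserved pad/OOV ids", {
  co <- manual_corpus(list(manual_user("u", 0, c("a a a b", "c c b z"))))
  v <- build_vocabulary(co)
  expect_identical(v$tokens[1:2], c("<pad>", "<unk>"))
  expect_identical(unname(v$token_ids[c("a", "b", "c", "z")]),
                   c(2L, 3L, 4L, 5L))  # freq 3,2,2,1; lexicographic ties
  expect_identical(unname(v$token_ids["<pad>"]), 0L)

  empty <- structure(list(users = list()), class = "mil_corpus")
  expect_length(build_vocabulary(empty)$tokens, 2L)

  # hand-built frequency table on a 20-token toy corpus
  toy <- manual_corpus(list(manual_user(
    "t", 0, c("sad sad sad happy happy ok", "sad ok ok go go go go sun",
              "sun sad happy go sun go"))))
  vt <- build_vocabulary(toy)
  counts <- sort(table(unlist(strsplit("sad sad sad happy happy ok sad ok ok go go go go sun sun sad happy go sun go", " "))), decreasing = TRUE)
  expect_identical(vt$tokens[-(1:2)][1:2], c("go", "sad"))  # 6 and 5 uses
  expect_identical(length(vt$tokens), length(counts) + 2L)
  expect_identical(vocab_lookup(vt, c("go", "notseen")),
                   c(unname(vt$token_ids["go"]), 1L))
})

test_that("bag encoding pads, masks, and keeps the most recent posts", {
  co <- manual_corpus(list(manual_user("u", 1, sprintf("post %d", 1:5))))
  v <- build_vocabulary(co)
  bag <- bag_encode(co$users[[1]], v, max_posts = 8, max_tokens = 5)
  expect_identical(bag$post_mask, c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L))
  expect_identical(bag$token_mask[1, ], c(1L, 1L, 0L, 0L, 0L))
  expect_true(all(bag$token_ids[bag$token_mask == 0L] == 0L))

  # over-capacity timeline: the most recent posts are retained
  co2 <- manual_corpus(list(manual_user("u", 1, sprintf("m%d", 1:25))))
  v2 <- build_vocabulary(co2)
  bag2 <- bag_encode(co2$users[[1]], v2, max_posts = 20, max_tokens = 3)
  expect_identical(bag2$n_posts, 20L)
  expect_identical(bag2$texts, sprintf("m%d", 6:25))

  expect_error(bag_encode(manual_user("v", 0, character()), v), "zero posts")
})

test_that("masked-out positions always carry id 0 on random corpora", {
  co <- tiny_corpus(n_pos = 6, n_ctl = 6, posts = 7, seed = 77)
  v <- build_vocabulary(co)
  for (bag in encode_corpus(co, v, max_posts = 10, max_tokens = 12)) {
    expect_true(all(bag$token_ids[bag$token_mask == 0L] == 0L))
    expect_true(all(bag$token_ids[bag$post_mask == 0L, ] == 0L))
    expect_identical(sum(bag$post_mask), min(bag$n_posts, 10L))
  }
})
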