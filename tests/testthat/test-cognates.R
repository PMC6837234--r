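test_that("normalize_form folds case, strips space, applies rules", {
  expect_equal(normalize_form("Farfar"), "farfar")
  expect_equal(normalize_form(" mor far "), "morfar")
  expect_equal(normalize_form("brat", rules = c(br = "B")), "Bat")
  # longest match wins over a shorter competing rule
  expect_equal(normalize_form("szczur", rules = c(s = "X", sz = "S", cz = "C")),
               "SCur")
  expect_error(normalize_form(""), "empty")
})

test_that("normalize_form is idempotent on random strings", {
  set.seed(7)
  for (i in 1:50) {
    s <- paste(sample(c(letters, LETTERS, " "), sample(1:12, 1),
                      replace = TRUE), collapse = "")
    if (!nzchar(trimws(s))) next
    n1 <- normalize_form(s)
    expect_identical(normalize_form(n1), n1)
  }
})

test_that("edit_distance matches the recursive oracle and is a semimetric", {
  expect_equal(edit_distance("farfar", "farfar"), 0)
  expect_equal(edit_distance("farfar", "morfar"), 2 / 6)
  expect_equal(edit_distance("a", "xyz"), 1)
  expect_error(edit_distance("", "a"), "non-empty")

  set.seed(11)
  alpha <- letters[1:6]
  for (i in 1:60) {
    a <- paste(sample(alpha, sample(1:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:8, 1), replace = TRUE), collapse = "")
    expect_equal(edit_distance(a, b),
                 lev_recursive(a, b) / max(nchar(a), nchar(b)))
    expect_equal(edit_distance(a, b), edit_distance(b, a))
    expect_equal(edit_distance(a, a), 0)
  }
})

test_that("distance_matrix is symmetric with zero diagonal", {
  expect_equal(distance_matrix("farfar"),
               matrix(0, 1, 1, dimnames = list("farfar", "farfar")))
  d <- distance_matrix(c("farfar", "morfar", "dziadek"))
  expect_equal(d, t(d))
  expect_equal(diag(d), c(farfar = 0, morfar = 0, dziadek = 0))
  expect_equal(d["farfar", "morfar"], 2 / 6)
  expect_gt(d["farfar", "dziadek"], 0.4)
  expect_gt(d["morfar", "dziadek"], 0.4)
})

test_that("flat_cluster handles the degenerate ends of the threshold", {
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(unname(flat_cluster(d0, 0.4)), rep(1L, 4))
  d1 <- random_dist(5)
  d1[d1 > 0] <- 0.9  # all off-diagonals above threshold
  expect_equal(unname(flat_cluster(d1, 0.4)), 1:5)
})

test_that("grandparent terms cluster as expected at the 0.4 threshold", {
  d <- distance_matrix(c(Swedish = "farfar", SwedishMF = "morfar",
                         Polish = "dziadek", English = "grandfather"))
  cl <- flat_cluster(d, 0.4)
  expect_equal(cl[["Swedish"]], cl[["SwedishMF"]])
  expect_length(unique(cl), 3)
  expect_false(cl[["Polish"]] == cl[["English"]])
})

test_that("flat_cluster agrees with hclust average linkage and is order-invariant", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    d <- random_dist(n)
    theta <- stats::runif(1, 0.2, 0.8)
    expect_true(same_partition(flat_cluster(d, theta), hclust_flat(d, theta)))
    perm <- sample(n)
    cl_perm <- flat_cluster(d[perm, perm], theta)
    expect_true(same_partition(cl_perm[rownames(d)], flat_cluster(d, theta)))
  }
})

test_that("single and complete linkage bracket average linkage", {
  set.seed(5)
  d <- random_dist(6)
  ns <- function(x) length(unique(x))
  expect_lte(ns(flat_cluster(d, 0.5, linkage = "single")),
             ns(flat_cluster(d, 0.5, linkage = "average")))
  expect_gte(ns(flat_cluster(d, 0.5, linkage = "complete")),
             ns(flat_cluster(d, 0.5, linkage = "average")))
})

test_that("overrides move occurrences, warn on unknowns, error on conflicts", {
  wl <- data.frame(language = c("Swedish", "Polish", "English"),
                   meaning = "FF",
                   form = c("farfar", "dziadek", "grandfather"))
  p <- code_cognates(wl, "FF")
  expect_equal(length(unique(p$class)), 3)

  expect_identical(apply_overrides(p, data.frame(meaning = character(),
                                                 language = character(),
                                                 form = character(),
                                                 class = character())), p)

  ov <- data.frame(meaning = "FF", language = "Polish", form = "dziadek",
                   class = as.character(p$class[p$language == "Swedish"]))
  p2 <- apply_overrides(p, ov)
  expect_equal(length(unique(p2$class)), 2)
  expect_equal(p2$class[p2$language == "Polish"],
               p2$class[p2$language == "Swedish"])
  expect_equal(p2$provenance[p2$language == "Polish"], "override")

  expect_warning(apply_overrides(p, data.frame(meaning = "FF",
                                               language = "Xx", form = "zz",
                                               class = "1")),
                 "unknown occurrence")

  ov_bad <- data.frame(meaning = "FF", language = rep("Polish", 2),
                       form = rep("dziadek", 2), class = c("1", "2"))
  expect_error(apply_overrides(p, ov_bad), "conflicting")
})

test_that("build_character densifies states in taxon order", {
  wl <- data.frame(language = c("Swedish", "Polish", "English"),
                   meaning = "FF",
                   form = c("farfar", "dziadek", "grandfather"))
  p <- code_cognates(wl, "FF")
  ch <- build_character(p, c("English", "Swedish", "Polish"))
  expect_equal(as.integer(ch)[1:3], c(0L, 1L, 2L))
  expect_equal(attr(ch, "meaning"), "FF")

  ch2 <- build_character(p, c("English", "Swedish", "Polish", "Latin"))
  expect_true(is.na(ch2[["Latin"]]))

  same <- data.frame(meaning = "B", language = c("x", "y", "z"),
                     form = "bror", class = 1L, provenance = "automatic")
  class(same) <- c("cognate_partition", "data.frame")
  chc <- build_character(same, c("x", "y", "z"))
  expect_equal(as.integer(chc), c(0L, 0L, 0L))
})

test_that("synonym policies keep first form or refuse", {
  wl <- data.frame(language = c("Swedish", "Swedish", "Polish"),
                   meaning = "FF", form = c("farfar", "morfar", "dziadek"))
  p <- code_cognates(wl, "FF", synonym_policy = "first")
  expect_equal(p$form[p$language == "Swedish"], "farfar")
  expect_error(code_cognates(wl, "FF", synonym_policy = "error"), "synonym")
})
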