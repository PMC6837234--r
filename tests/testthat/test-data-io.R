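test_that("read_wordlist validates and fills in classes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("language,meaning,form",
               "Swedish,FF,farfar",
               "Polish,FF,dziadek",
               "English,FF,grandfather"), f)
  wl <- read_wordlist(f)
  expect_equal(nrow(wl), 3)
  expect_true(all(wl$lexical_class == "swadesh"))  # FF not in the 10-type set

  writeLines(c("language,meaning,form", "Swedish,M,mor"), f)
  expect_equal(read_wordlist(f)$lexical_class, "kin")

  writeLines("language,meaning,form", f)
  expect_equal(nrow(read_wordlist(f)), 0)

  writeLines(c("language,meaning,form", "Swedish,FF,farfar",
               "Swedish,FF,farfar"), f)
  expect_error(read_wordlist(f), "line\\(s\\) 3")

  writeLines(c("language,form", "Swedish,farfar"), f)
  expect_error(read_wordlist(f), "meaning")

  writeLines(c("language,meaning,form", "Swedish,FF,"), f)
  expect_error(read_wordlist(f), "empty form")
})

test_that("tree samples read from newick and nexus, rejecting bad trees", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:100,B:100):50,C:150);", f)
  ts <- read_tree_sample(f, "newick")
  expect_s3_class(ts, "tree_sample")
  expect_equal(length(ts$trees), 1)
  d <- ape::node.depth.edgelength(ts$trees[[1]])
  expect_equal(unname(d[1:3]), rep(150, 3))

  nx <- withr::local_tempfile(fileext = ".nex")
  tr <- ts$trees[[1]]
  ape::write.nexus(c(tr, tr), file = nx)
  ts2 <- read_tree_sample(nx, "nexus")
  expect_equal(length(ts2$trees), 2)
  expect_equal(ts2$taxa, c("A", "B", "C"))

  writeLines("((A:-5,B:100):50,C:150);", f)
  expect_error(read_tree_sample(f, "newick"), "negative")

  writeLines("(A:100,B:100,C:150);", f)  # basal trichotomy = unrooted
  expect_error(read_tree_sample(f, "newick"), "rooted")
})

test_that("pruning preserves path lengths among retained leaves", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(prune_to_taxa(tr, c("A", "B", "C")), tr)

  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  d <- ape::node.depth.edgelength(pr)
  expect_equal(unname(d[seq_len(2)]), c(2, 2))

  # random trees: all pairwise distances among kept leaves unchanged
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    tr <- random_tree(n)
    keep <- sample(tr$tip.label, sample(2:(n - 1), 1))
    full_d <- ape::cophenetic.phylo(tr)[keep, keep]
    prun_d <- ape::cophenetic.phylo(prune_to_taxa(tr, keep))[keep, keep]
    expect_equal(prun_d, full_d, tolerance = 1e-10)
  }

  toy <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(prune_to_taxa(toy, c("A", "Z")), "not in tree")
  expect_error(prune_to_taxa(toy, "A"), "at least 2")
})

test_that("frequency and override tables are validated with line locations", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("language,word,meaning,corpus_id,corpus_type,count,corpus_size",
               "sv,mor,M,c1,spoken,10,1000"), f)
  expect_equal(nrow(read_frequency_table(f)), 1)

  writeLines(c("language,word,meaning,corpus_id,corpus_type,count,corpus_size",
               "sv,mor,M,c1,spoken,2000,1000"), f)
  expect_error(read_frequency_table(f), "exceeds corpus_size.*2")

  writeLines(c("language,word,meaning,corpus_id,corpus_type,count,corpus_size",
               "sv,mor,M,c1,radio,10,1000"), f)
  expect_error(read_frequency_table(f), "corpus_type")

  writeLines(c("meaning,language,form,class",
               "FF,Polish,dziadek,1",
               "FF,Polish,dziadek,2"), f)
  expect_error(read_overrides(f), "duplicate override")
})

test_that("character matrices round-trip through NEXUS losslessly", {
  ch1 <- multistate_character(c(A = 0L, B = 1L, C = NA, D = 2L), "FF")
  ch2 <- multistate_character(c(A = 0L, B = 0L, C = 0L, D = 1L), "MZ")
  f <- withr::local_tempfile(fileext = ".nex")
  write_character_matrix(list(FF = ch1, MZ = ch2), f)
  back <- read_character_matrix(f)
  expect_equal(names(back), c("FF", "MZ"))
  expect_equal(unclass(back$FF), unclass(ch1), ignore_attr = TRUE)
  expect_equal(as.integer(back$FF), as.integer(ch1))
  expect_equal(names(back$FF), names(ch1))
  expect_equal(as.integer(back$MZ), as.integer(ch2))
  expect_equal(attr(back$FF, "meaning"), "FF")
})

test_that("multistate_character enforces naming and state validity", {
  expect_error(multistate_character(c(0, 1)), "named")
  expect_error(multistate_character(c(A = -1)), "non-negative")
  ch <- multistate_character(c(A = 0, B = 1, C = NA))
  expect_equal(sum(is.na(ch)), 1)
})
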