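test_that("signed permutations validate their invariants", {
  expect_error(signed_permutation(c(1, 0, 2)), "nonzero")
  expect_error(signed_permutation(c(1, -1)), "distinct")
  expect_error(signed_permutation(integer(0)), "at least one")
  expect_error(breakpoint_distance(c(1, 2), c(1, 3)), "magnitude set")
})

test_that("breakpoint distance counts broken signed adjacencies", {
  expect_equal(breakpoint_distance(c(1, 2, 3), c(1, 2, 3)), 0L)
  expect_equal(breakpoint_distance(c(1, -2, 3), c(1, 2, 3)), 2L)
  expect_equal(breakpoint_distance(c(-3, -2, -1), c(1, 2, 3)), 2L)  # caps
  set.seed(41)
  for (i in 1:25) {
    p <- random_signed_perm(8); q <- random_signed_perm(8)
    expect_equal(breakpoint_distance(p, q), breakpoint_distance(q, p))
  }
})

test_that("inversion distance handles canonical small cases", {
  expect_equal(inversion_distance(c(1, 2, 3), c(1, 2, 3)), 0L)
  expect_equal(inversion_distance(-1L, 1L), 1L)
  expect_equal(inversion_distance(c(1, -2, 3), 1:3), 1L)
  ## the minimal hurdle: all-positive transposed pair needs 3 reversals
  expect_equal(inversion_distance(c(2, 1), c(1, 2)), 3L)
  expect_equal(inversion_distance_bfs(c(2, 1), c(1, 2)), 3L)
  ## known hurdle family (all-positive decreasing) agrees with the oracle
  for (n in 3:6) {
    expect_equal(inversion_distance(rev(seq_len(n)), seq_len(n)),
                 inversion_distance_bfs(rev(seq_len(n)), seq_len(n)))
  }
  expect_error(inversion_distance_bfs(c(2, 1), c(1, 2), limit = 2L),
               "limit exceeded")
})

test_that("both distances satisfy metric axioms and the bp/2 bound", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:9, 1)
    p <- random_signed_perm(n); q <- random_signed_perm(n)
    r <- random_signed_perm(n)
    dpq <- inversion_distance(p, q)
    expect_equal(dpq, inversion_distance(q, p))
    expect_equal(inversion_distance(p, p), 0L)
    if (dpq == 0L) expect_identical(as.integer(p), as.integer(q))
    expect_lte(dpq, inversion_distance(p, r) + inversion_distance(r, q))
    b <- breakpoint_distance(p, q)
    expect_equal(b, breakpoint_distance(q, p))
    expect_lte(b, breakpoint_distance(p, r) + breakpoint_distance(r, q))
    expect_gte(dpq, ceiling(b / 2))
  }
})

test_that("sorting scenarios are parsimonious and replayable", {
  expect_equal(length(sorting_scenario(c(1, 2, 3), c(1, 2, 3))), 0L)
  expect_equal(sorting_scenario(c(1, -2, 3), 1:3), list(c(2L, 2L)))
  set.seed(13)
  for (i in 1:60) {
    p <- random_signed_perm(10); q <- random_signed_perm(10)
    sc <- sorting_scenario(p, q)
    expect_equal(length(sc), inversion_distance(p, q))
    r <- plastidyn:::.compose_relative(p, q)
    for (ev in sc) r <- plastidyn:::.reverse_segment(r, ev[1], ev[2])
    expect_equal(as.integer(r), seq_len(10L))
  }
})

test_that("pairwise distance tables are symmetric with zero diagonal", {
  perms <- lapply(1:4, function(i) {
    signed_permutation(1:6, taxon = paste0("t", i), frame = "f")
  })
  dt <- pairwise_distance_matrix(perms)
  expect_true(all(dt$bp == 0L) && all(dt$iv == 0L))
  expect_error(pairwise_distance_matrix(list(perms[[1]], perms[[1]])),
               "duplicate")
  set.seed(3)
  perms2 <- lapply(1:5, function(i) {
    signed_permutation(random_signed_perm(8), taxon = paste0("s", i),
                       frame = "f")
  })
  dt2 <- pairwise_distance_matrix(perms2)
  expect_identical(dt2$iv, t(dt2$iv))
  expect_identical(dt2$bp, t(dt2$bp))
  expect_true(all(diag(dt2$iv) == 0L) && all(diag(dt2$bp) == 0L))

  dir <- withr::local_tempdir()
  write_distance_table(dt2, file.path(dir, "d.tsv"))
  lines <- readLines(file.path(dir, "d.tsv"))
  expect_length(lines, 6L)
  expect_match(lines[3], "^s2\t\\d+/\\d+\t-$")
})

test_that("permutation TSV round-trips", {
  perms <- list(signed_permutation(c(3, -1, 2), "tax1", "frameX"),
                signed_permutation(c(-2, 1, 3), "tax2", "frameX"))
  dir <- withr::local_tempdir()
  write_permutations(perms, file.path(dir, "p.tsv"))
  back <- read_permutations(file.path(dir, "p.tsv"))
  expect_equal(back[[1]]$blocks, c(3L, -1L, 2L))
  expect_equal(back[[2]]$taxon, "tax2")
  expect_equal(back[[2]]$frame, "frameX")
})

test_that("gene orders encode to signed block permutations", {
  a <- mk_gene_record("a", paste0("g", 1:7), rep("+", 7),
                      seq(0L, 600L, 100L))
  ident <- encode_lcb_permutations(a, a)
  expect_equal(ident[[1]]$blocks, 1L)     # one merged block
  expect_equal(ident[[2]]$blocks, 1L)

  b <- mk_gene_record("b", c("g1", "g2", "g5", "g4", "g3", "g6", "g7"),
                      c("+", "+", "-", "-", "-", "+", "+"),
                      seq(0L, 600L, 100L))
  pp <- encode_lcb_permutations(a, b)
  expect_equal(pp[[1]]$blocks, 1:3)
  expect_equal(pp[[2]]$blocks, c(1L, -2L, 3L))

  expect_error(encode_lcb_permutations(
    a, mk_gene_record("c", c("zz1", "zz2"), c("+", "+"), c(0L, 100L))),
    "fewer than 2")
})

test_that("simulated gene-order histories bound the encoded distance", {
  base <- mk_gene_record("anc", paste0("g", 1:20), rep("+", 20),
                         seq(0L, by = 100L, length.out = 20))
  for (s in 1:20) {
    h <- simulate_inversion_history(
      signed_permutation(1:20, "anc", "f"), 2L, seed = s)
    derived_order <- h$end_perm$blocks
    b <- mk_gene_record("der", paste0("g", abs(derived_order)),
                        ifelse(derived_order > 0, "+", "-"),
                        seq(0L, by = 100L, length.out = 20))
    pp <- encode_lcb_permutations(base, b)
    expect_lte(inversion_distance(pp[[1]], pp[[2]]), 2L)
  }
})

test_that("segment inversion is an involution and flips structure class", {
  rec <- small_architecture("inverted", small = FALSE, seed = 31L)
  f <- rec$features
  bigB <- f[f$id == "big_rep_B", ]
  iv <- c(bigB$start, bigB$end)          # spans exactly one big copy
  flipped <- apply_inversion(rec, iv)
  expect_equal(classify_master_structure(rec), "IR")
  expect_equal(classify_master_structure(flipped), "DR")
  back <- apply_inversion(flipped, iv)
  expect_identical(back$sequence, rec$sequence)
  expect_equal(back$features[order(back$features$id), ]$start,
               f[order(f$id), ]$start)

  recD <- small_architecture("direct", small = FALSE, seed = 32L)
  fD <- recD$features; bigBD <- fD[fD$id == "big_rep_B", ]
  expect_equal(classify_master_structure(
    apply_inversion(recD, c(bigBD$start, bigBD$end))), "IR")

  expect_error(apply_inversion(rec, c(bigB$start + 5L, bigB$end)),
               "bisects")
})
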