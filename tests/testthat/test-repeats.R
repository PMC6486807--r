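test_that("planted direct and inverted pairs are found with exact extent", {
  base <- rand_dna(20000, seed = 71)
  unit <- substr(base, 3001, 3100)
  s <- base
  substr(s, 12001, 12100) <- unit
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 5001, 5100))))
  substr(s, 15001, 15100) <- rc
  ## block chance extension at the planted boundaries
  substr(s, 3000, 3000) <- "A";  substr(s, 12000, 12000) <- "C"
  substr(s, 3101, 3101) <- "A";  substr(s, 12101, 12101) <- "C"
  substr(s, 5000, 5000) <- "A";  substr(s, 15101, 15101) <- "C"
  substr(s, 5101, 5101) <- "A";  substr(s, 15000, 15000) <- "C"
  rec <- genome_record("t", s, topology = "linear")
  rp <- find_repeats(rec, min_len = 25L)
  d <- rp[rp$orientation == "direct", ]
  i <- rp[rp$orientation == "inverted", ]
  expect_equal(nrow(d), 1L)
  expect_equal(nrow(i), 1L)
  expect_equal(c(d$start_a, d$end_a, d$start_b, d$end_b),
               c(3000L, 3100L, 12000L, 12100L))
  expect_equal(c(i$start_a, i$end_a, i$start_b, i$end_b),
               c(5000L, 5100L, 15000L, 15100L))
  expect_equal(c(d$length, i$length), c(100L, 100L))
  expect_equal(i$strand_b, "-")
})

test_that("reported pairs are maximal (not extendable by one base)", {
  rec <- small_architecture("inverted", seed = 44L)
  rp <- find_repeats(rec, min_len = 50L)
  s2 <- paste0(rec$sequence, rec$sequence)   # circular indexing helper
  at <- function(p) substr(s2, p + 1L, p + 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in seq_len(nrow(rp))) {
    if (rp$copies[r] > 2L) next
    a <- rp$start_a[r]; b <- rp$start_b[r]; len <- rp$length[r]
    L <- nchar(rec$sequence)
    if (rp$orientation[r] == "direct") {
      expect_false(at((a - 1) %% L) == at((b - 1) %% L))
      expect_false(at((a + len) %% L) == at((b + len) %% L))
    } else {
      expect_false(at((a - 1) %% L) == comp[[at((b + len) %% L)]])
      expect_false(at((a + len) %% L) == comp[[at((b - 1) %% L)]])
    }
  }
})

test_that("a repeat wrapping the circular origin is still recovered", {
  base <- rand_dna(12000, seed = 88)
  unit <- substr(base, 4001, 4120)       # 120 bp
  s <- base
  ## plant second copy across the origin: last 60 bp + first 60 bp
  substr(s, 11941, 12000) <- substr(unit, 1, 60)
  substr(s, 1, 60) <- substr(unit, 61, 120)
  ## block chance extension at both pairs of flanks
  substr(s, 4000, 4000) <- "A";  substr(s, 11940, 11940) <- "C"
  substr(s, 4121, 4121) <- "A";  substr(s, 61, 61) <- "C"
  rec <- genome_record("c", s, topology = "circular")
  rp <- find_repeats(rec, min_len = 50L)
  hit <- rp[rp$length >= 120L & rp$copies == 2L, ]
  expect_gte(nrow(hit), 1L)
  expect_true(any(hit$length == 120L &
                    (hit$start_a %% 12000L == 11940L |
                       hit$start_b %% 12000L == 11940L |
                       hit$start_a == 4000L | hit$start_b == 4000L)))
})

test_that("tandem arrays collapse to unit length and copy number", {
  base <- rand_dna(9000, seed = 72)
  unit <- rand_dna(17, seed = 73)
  s <- paste0(substr(base, 1, 4000), strrep(unit, 16),
              substr(base, 4273, 9000))
  rec <- genome_record("t", s, topology = "linear")
  rp <- find_repeats(rec, min_len = 15L)
  arr <- rp[rp$copies > 2L, ]
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$length, 17L)
  expect_equal(arr$copies, 16L)
  ## the array's internal pairings are not double-reported
  expect_equal(sum(rp$start_a >= 3990 & rp$start_a <= 4290), 1L)
})

test_that("detection is strand-symmetric", {
  rec <- small_architecture("direct", seed = 45L)
  rp1 <- find_repeats(rec, min_len = 100L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rec$sequence)))
  rec2 <- genome_record(rec$id, rc, topology = "circular")
  rp2 <- find_repeats(rec2, min_len = 100L)
  expect_equal(nrow(rp1), nrow(rp2))
  expect_equal(sort(rp1$length), sort(rp2$length))
  expect_equal(table(rp1$orientation), table(rp2$orientation))
})

test_that("random sequence yields no spurious long repeats", {
  for (s in 1:20) {
    rp <- find_repeats(genome_record("r", rand_dna(20000, seed = 500 + s),
                                     topology = "linear"), min_len = 24L)
    expect_equal(nrow(rp), 0L)
  }
})

test_that("argument validation and summaries behave", {
  expect_error(find_repeats(rand_dna(1000, seed = 1), min_len = 3L),
               "seed width")
  expect_error(repeat_summary(data.frame(), breaks = c(30, 15)), "ordered")

  pairs <- data.frame(length = c(48L, 60L, 20L, 1500L),
                      orientation = c("direct", "inverted", "direct",
                                      "direct"))
  sm <- repeat_summary(pairs)
  expect_equal(sum(sm$Freq), 3L)          # the 1.5 kb DR copy is excluded
  expect_equal(sm$Freq[sm$bin == "(30,50]" & sm$orientation == "direct"], 1L)
  expect_equal(sm$Freq[sm$bin == "(50,Inf]" & sm$orientation == "inverted"],
               1L)
  empty <- repeat_summary(data.frame(length = integer(),
                                     orientation = character()))
  expect_true(all(empty$Freq == 0L))
  ## planted count bookkeeping: n pairs in, n counted
  many <- data.frame(length = rep(40L, 42), orientation = "direct")
  expect_equal(sum(repeat_summary(many)$Freq), 42L)
})

test_that("the large repeat pair is identified or absence reported", {
  fx <- small_architecture("direct", seed = 46L)
  pair <- large_repeat_pair(fx)
  expect_equal(pair$length, 1500L)
  expect_equal(pair$orientation, "direct")
  ## annotation absent: fall back to detection
  naked <- genome_record(fx$id, fx$sequence, topology = "circular")
  det <- large_repeat_pair(naked)
  expect_equal(det$length, 1500L)
  ## longest pair wins over the small one
  expect_equal(pair$pair_id, "big_repeat")

  rnd <- genome_record("r", rand_dna(50000, seed = 47), topology = "linear")
  expect_error(large_repeat_pair(rnd), "no quadripartite structure")
})
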