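test_that("canonical keys are rotation- and reflection-invariant", {
  set.seed(17)
  for (i in 1:40) {
    f <- random_molecule_form(n_single = sample(2:5, 1),
                              n_pairs = sample(1:3, 1), seed = i)
    k <- canonical_key(f)
    n <- length(f$tokens)
    r <- sample(n, 1)
    idx <- c(seq(r, n), if (r > 1) seq_len(r - 1))
    rot <- molecule_form(f$tokens[idx], f$orient[idx])
    expect_identical(canonical_key(rot), k)
    refl <- molecule_form(rev(f$tokens[idx]), -rev(f$orient[idx]))
    expect_identical(canonical_key(refl), k)
  }
})

test_that("flip is an involution and demands an inverted pair", {
  m <- molecule_form(c("L1", "s", "L2", "B", "S1", "s", "S2", "B"),
                     c(1L, 1L, 1L, 1L, 1L, -1L, 1L, -1L))
  f1 <- flip(m, "B")
  expect_identical(canonical_key(flip(f1, "B")), canonical_key(m))
  expect_equal(pair_orientation(f1, "s"), "direct")   # isomer I geometry
  f2 <- flip(m, "s")
  expect_equal(pair_orientation(f2, "B"), "direct")   # isomer II geometry
  expect_error(flip(f1, "s"), "not inverted")
  ## either arc gives the same canonical child
  pos <- which(m$tokens == "B")
  idx <- c(seq(pos[2], length(m$tokens)), seq_len(pos[2] - 1L))
  rot <- molecule_form(m$tokens[idx], m$orient[idx])
  expect_identical(canonical_key(flip(rot, "B")), canonical_key(f1))
})

test_that("split conserves the segment multiset and needs a direct pair", {
  m <- molecule_form(c("B", "LSC", "B", "SSC"), c(1L, 1L, 1L, 1L))
  ch <- split_at(m, "B")
  expect_length(ch, 2L)
  expect_true(all(vapply(ch, function(x) x$kind, "") == "subgenomic"))
  joint <- sort(c(ch[[1]]$tokens, ch[[2]]$tokens))
  expect_equal(joint, sort(m$tokens))     # copies counted once per child
  expect_error(split_at(molecule_form(c("B", "L", "B", "S"),
                                      c(1L, 1L, -1L, 1L)), "B"),
               "not direct")
})

test_that("state graphs reproduce the canonical DR/IR architectures", {
  fx <- fixture_figure5()
  g_dr <- enumerate_forms(fx$DR_only)
  fc <- form_counts(g_dr)
  expect_equal(fc$full_length, 1L)
  expect_equal(fc$subgenomic, 2L)
  expect_equal(classify_dynamic(g_dr), "DR_only")
  expect_equal(unname(stoichiometry(g_dr)), 1)

  g_un <- enumerate_forms(fx$IRDR_uncinata)
  fc_un <- form_counts(g_un)
  expect_equal(fc_un$full_length, 3L)
  expect_equal(fc_un$split_children, 4L)  # 2 per direct-pair-bearing isomer
  expect_equal(classify_dynamic(g_un), "IRDR_coexisting")
  expect_equal(unname(stoichiometry(g_un)), rep(1 / 3, 3))

  g_bi <- enumerate_forms(fx$DRIR_bisulcata)
  expect_equal(form_counts(g_bi)$full_length, 3L)
  expect_equal(classify_dynamic(g_bi), "IRDR_coexisting")

  ## IR-only: big inverted pair, no small pair -> 2 isomers, no subgenomes
  ir_only <- small_architecture("inverted", small = FALSE, seed = 61L)
  g_ir <- enumerate_forms(ir_only)
  fc_ir <- form_counts(g_ir)
  expect_equal(fc_ir$full_length, 2L)
  expect_equal(fc_ir$subgenomic, 0L)
  expect_equal(classify_dynamic(g_ir), "IR_only")
})

test_that("master classification matches annotation and inversion toggles it", {
  fx <- fixture_figure5()
  expect_equal(classify_master_structure(fx$DR_only), "DR")
  expect_equal(classify_master_structure(fx$IRDR_uncinata), "IR")
  expect_equal(classify_master_structure(fx$DRIR_bisulcata), "DR")
})

test_that("enumeration is independent of the starting isomer", {
  set.seed(23)
  n_ok <- 0L
  for (i in 1:30) {
    f <- random_molecule_form(n_single = sample(2:4, 1),
                              n_pairs = sample(1:2, 1), seed = 100 + i)
    g <- enumerate_forms(f)
    full <- Filter(function(x) x$kind == "full_length", g$forms)
    keys <- sort(names(g$forms))
    for (alt in full) {
      g2 <- enumerate_forms(molecule_form(alt$tokens, alt$orient))
      expect_identical(sort(names(g2$forms)), keys)
    }
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 30L)
})

test_that("flip involution and split conservation hold across random graphs", {
  for (i in 1:25) {
    f <- random_molecule_form(n_single = sample(2:5, 1),
                              n_pairs = sample(1:3, 1), seed = 300 + i)
    g <- enumerate_forms(f)
    ev <- g$events
    for (e in seq_len(nrow(ev))) {
      parent <- g$forms[[ev$parent[e]]]
      if (ev$type[e] == "flip") {
        child <- flip(parent, ev$pair_id[e])
        expect_identical(canonical_key(child), ev$child1[e])
        expect_identical(canonical_key(flip(child, ev$pair_id[e])),
                         ev$parent[e])
      } else {
        ch <- split_at(parent, ev$pair_id[e])
        joint <- sort(c(ch[[1]]$tokens, ch[[2]]$tokens))
        expect_equal(joint, sort(parent$tokens))
      }
    }
  }
})

test_that("runaway enumeration is guarded", {
  f <- random_molecule_form(n_single = 4L, n_pairs = 3L, seed = 5L)
  expect_error(enumerate_forms(f, max_forms = 1L), "runaway")
})

test_that("inverting across one large-repeat copy exchanges the 5b/5a graphs", {
  dr <- small_architecture("direct", small = FALSE, seed = 62L)
  f <- dr$features
  bigB <- f[f$id == "big_rep_B", ]
  ir <- apply_inversion(dr, c(bigB$start, bigB$end))
  g_dr <- enumerate_forms(dr)
  g_ir <- enumerate_forms(ir)
  expect_equal(classify_dynamic(g_dr), "DR_only")
  expect_equal(classify_dynamic(g_ir), "IR_only")
  seg <- function(g) sort(g$segments$token)
  expect_equal(seg(g_dr), seg(g_ir))      # same segment set, opposite class
})
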