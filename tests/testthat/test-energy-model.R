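params <- energy_parameters()

test_that("stacking table covers all 36 motifs and obeys strand-exchange symmetry", {
  tab <- default_stack_table()
  expect_false(anyNA(tab))
  rev_bp <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p1 in rownames(tab)) {
    for (p2 in colnames(tab)) {
      expect_equal(tab[p1, p2], tab[rev_bp(p2), rev_bp(p1)])
    }
  }
})

test_that("perfect complement forms a full helix matching the oracle", {
  mfe <- duplex_mfe("GGGGG", "CCCCC", params)
  expect_valid_interaction(mfe, "GGGGG", "CCCCC", params)
  expect_identical(nrow(mfe$pairs), 5L)
  expect_identical(mfe$pairs$pos_a, 1:5)
  expect_identical(mfe$pairs$pos_b, 5:1)
  oracle <- brute_force_duplex_mfe("GGGGG", "CCCCC", params)
  expect_equal(mfe$e_total, oracle$e_total, tolerance = 1e-9)
  # 4 GC-on-GC stacks plus initiation, from the embedded table
  expect_equal(mfe$e_total, 4.09 + 4 * params$stack["GC", "GC"],
               tolerance = 1e-9)
})

test_that("unpairable or unfavourable inputs yield no interaction", {
  expect_null(duplex_mfe("AAAA", "AAAA", params))
  expect_null(brute_force_duplex_mfe("AAAA", "AAAA", params))
  # a lone GC pair costs the initiation penalty and is never favourable
  expect_null(duplex_mfe("G", "C", params))
  expect_null(brute_force_duplex_mfe("G", "C", params))
  # GC vs GC: best configuration is the 2-pair stack at +0.67, still >= 0
  expect_null(duplex_mfe("GC", "GC", params))
  bb <- brute_force_boundary_minima("GC", "GC", params)
  expect_equal(min(bb$e_total), params$init_penalty + params$stack["GC", "CG"],
               tolerance = 1e-9)
  expect_equal(min(bb$e_total), 0.67, tolerance = 1e-9)
})

test_that("dynamic program equals the exhaustive oracle on random pairs", {
  set.seed(101)
  for (k in 1:30) {
    a <- rand_rna(sample(4:12, 1))
    b <- rand_rna(sample(4:12, 1))
    m <- duplex_mfe(a, b, params)
    o <- brute_force_duplex_mfe(a, b, params)
    if (is.null(o)) {
      expect_null(m)
    } else {
      expect_equal(m$e_total, o$e_total, tolerance = 1e-9,
                   label = sprintf("mfe(%s, %s)", a, b))
      expect_valid_interaction(m, a, b, params)
    }
  }
})

test_that("accessibility penalties never make the reported MFE more stable", {
  set.seed(202)
  for (k in 1:15) {
    a <- rand_rna(sample(6:12, 1)); b <- rand_rna(sample(6:12, 1))
    m0 <- duplex_mfe(a, b, params)
    if (is.null(m0)) next
    for (acc in list(acc_constant(0.2), acc_constant(1))) {
      m1 <- duplex_mfe(a, b, params, acc)
      if (!is.null(m1)) expect_gte(m1$e_total, m0$e_total - 1e-9)
    }
  }
})

test_that("constant-accessibility optimum matches the oracle", {
  set.seed(303)
  acc <- acc_constant(0.3)
  for (k in 1:10) {
    a <- rand_rna(sample(5:10, 1)); b <- rand_rna(sample(5:10, 1))
    m <- duplex_mfe(a, b, params, acc)
    o <- brute_force_duplex_mfe(a, b, params, acc)
    if (is.null(o)) expect_null(m)
    else expect_equal(m$e_total, o$e_total, tolerance = 1e-9)
  }
})

test_that("window-table accessibility is honoured exactly on small inputs", {
  tab <- data.frame(id = c("A", "B"), start = c(1, 1), end = c(5, 5),
                    ed = c(2.5, 1.5))
  acc <- acc_table(tab)
  sa <- rna_seq("GGGGG", "A"); sb <- rna_seq("CCCCC", "B")
  m <- duplex_mfe(sa, sb, params, acc)
  o <- brute_force_duplex_mfe(sa, sb, params, acc)
  expect_equal(m$e_total, o$e_total, tolerance = 1e-9)
  expect_equal(m$ed_a + m$ed_b, 4.0, tolerance = 1e-9)
  # provider contract: empty window is free, listed window exact
  expect_identical(acc$ed(sa, 3, 2), 0)
  expect_equal(acc$ed(sa, 1, 5), 2.5)
})

test_that("role exchange reports the same energy with swapped coordinates", {
  set.seed(404)
  for (k in 1:10) {
    a <- rand_rna(sample(5:12, 1)); b <- rand_rna(sample(5:12, 1))
    m1 <- duplex_mfe(a, b, params)
    m2 <- duplex_mfe(b, a, params)
    if (is.null(m1)) {
      expect_null(m2)
    } else {
      expect_equal(m1$e_total, m2$e_total, tolerance = 1e-9)
      expect_setequal(paste(m1$pairs$pos_a, m1$pairs$pos_b),
                      paste(m2$pairs$pos_b, m2$pairs$pos_a))
    }
  }
})

test_that("suboptimal list is energy-sorted, boundary-unique, favourable, MFE-headed", {
  subs <- enumerate_suboptimals("GGGGG", "CCCCC", params, max_count = 100)
  e <- vapply(subs, `[[`, numeric(1), "e_total")
  expect_false(is.unsorted(e))
  expect_true(all(e < 0))
  bounds <- vapply(subs, function(x) {
    paste(x$start_a, x$end_a, x$start_b, x$end_b)
  }, character(1))
  expect_identical(anyDuplicated(bounds), 0L)
  mfe <- duplex_mfe("GGGGG", "CCCCC", params)
  expect_equal(subs[[1]]$e_total, mfe$e_total, tolerance = 1e-9)
  expect_identical(subs[[1]]$pairs, mfe$pairs)
  # per-boundary energies match the exhaustive oracle (joined on the
  # boundary quadruple: float-equal energies may order ties differently)
  bb <- brute_force_boundary_minima("GGGGG", "CCCCC", params)
  bb <- bb[bb$e_total < 0, ]
  expect_identical(length(subs), nrow(bb))
  expect_equal(e, bb$e_total, tolerance = 1e-9)
  got <- data.frame(
    start_a = vapply(subs, `[[`, integer(1), "start_a"),
    end_a = vapply(subs, `[[`, integer(1), "end_a"),
    start_b = vapply(subs, `[[`, integer(1), "start_b"),
    end_b = vapply(subs, `[[`, integer(1), "end_b"),
    e_total = e)
  joined <- merge(got, bb, by = c("start_a", "end_a", "start_b", "end_b"))
  expect_identical(nrow(joined), nrow(bb))
  expect_equal(joined$e_total.x, joined$e_total.y, tolerance = 1e-9)
})

test_that("suboptimal enumeration respects regions and degenerate inputs", {
  expect_identical(enumerate_suboptimals("AAAA", "AAAA", params), list())
  subs1 <- enumerate_suboptimals("GGGGG", "CCCCC", params, max_count = 1)
  mfe <- duplex_mfe("GGGGG", "CCCCC", params)
  expect_length(subs1, 1L)
  expect_equal(subs1[[1]]$e_total, mfe$e_total, tolerance = 1e-9)
  region <- list(a = c(2, 4), b = c(2, 4))
  subs <- enumerate_suboptimals("GGGGG", "CCCCC", params, max_count = 50,
                                region = region)
  for (s in subs) {
    expect_true(all(s$pairs$pos_a >= 2 & s$pairs$pos_a <= 4))
    expect_true(all(s$pairs$pos_b >= 2 & s$pairs$pos_b <= 4))
  }
  # the region head is the region-restricted optimum
  bb <- brute_force_boundary_minima("GGGGG", "CCCCC", params)
  bb <- bb[bb$start_a >= 2 & bb$end_a <= 4 & bb$start_b >= 2 &
             bb$end_b <= 4 & bb$e_total < 0, ]
  expect_equal(subs[[1]]$e_total, min(bb$e_total), tolerance = 1e-9)
})

test_that("oracle refuses sequences beyond its exhaustive-size guard", {
  expect_error(brute_force_duplex_mfe(strrep("G", 13), "CCC", params),
               "12 nt")
})

test_that("area guard directs long unrestricted suboptimal enumerations to regions", {
  long <- strrep("ACGU", 30)  # 120 nt; 120 * 120 > 4096
  expect_error(enumerate_suboptimals(long, long, params), "region")
})
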