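params <- energy_parameters()

make_table <- function(n, seed = 1, site_length = 8L, flank = 8L,
                       path = withr::local_tempfile(fileext = ".csv",
                                                    .local_envir = parent.frame())) {
  spec <- fixture_spec(site_length = site_length, gc_fraction = 0.75,
                       flank_length_a = flank, flank_length_b = flank,
                       seed = seed)
  generate_known_com_table(n, spec, path = path)
  path
}

test_that("mutation-type classes are lex-sorted and role-symmetric", {
  expect_identical(mutation_type_class("AU", "CG"), "AUCG")
  expect_identical(mutation_type_class("UA", "GC"), "AUCG")
  expect_identical(mutation_type_class("GC", "CG"), "CGCG")
  # invariant under swapping the two sequences' roles
  for (wt in c("AU", "UA", "GC", "CG", "GU", "UG")) {
    for (mut in c("AU", "UA", "GC", "CG", "GU", "UG")) {
      swapped_wt <- paste0(substr(wt, 2, 2), substr(wt, 1, 1))
      swapped_mut <- paste0(substr(mut, 2, 2), substr(mut, 1, 1))
      expect_identical(mutation_type_class(wt, mut),
                       mutation_type_class(swapped_wt, swapped_mut))
    }
  }
})

test_that("known-CoM tables are read, validated, and tallied", {
  path <- make_table(3, seed = 31)
  records <- read_known_coms(path)
  expect_length(records, 3L)
  expect_identical(records[[1]]$pair_id, "synth001")
  expect_identical(nrow(records[[1]]$coms), 1L)
  # known CoMs are GC flips by construction: only the CGCG class
  tally <- mutation_type_tally(records)
  expect_identical(tally$class, "CGCG")
  expect_identical(tally$count, 3L)
  # wildtype mismatch is rejected
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$wt_bp[1] <- "AU"
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, bad, row.names = FALSE)
  expect_error(read_known_coms(bad), "does not match")
  # a compatible "mutation" (a wildtype base can still pair a mutant) is
  # rejected: wildtype G wobble-pairs mutant U of AU / mutant U of UA
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$mut_bp <- ifelse(substr(tab$wt_bp, 1, 1) == "G", "AU", "UA")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, bad2, row.names = FALSE)
  expect_error(read_known_coms(bad2), "compatibility")
})

test_that("the CoM-containing interaction rank follows the energy-sorted list", {
  # CoM inside the implanted (MFE) site: rank 1
  path <- make_table(2, seed = 32)
  records <- read_known_coms(path)
  for (r in records) {
    expect_identical(com_rri_rank(r, params), 1L)
  }
  # a base pair only realized in the 2nd-best boundary pattern: rank 2.
  # On GGGGG/CCCCC the MFE is the full 5-pair helix (pairs i + j = 6); the
  # oracle's per-boundary list puts boundary (1,4,1,4) second, whose best
  # pattern pairs (1,4).
  bb <- brute_force_boundary_minima("GGGGG", "CCCCC", params)
  bb <- bb[bb$e_total < 0, ]
  expect_identical(unlist(bb[2, c("start_a", "end_a", "start_b", "end_b")]),
                   c(start_a = 1L, end_a = 4L, start_b = 1L, end_b = 4L))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(pair_id = "p1", seq_a = "GGGGG",
                              seq_b = "CCCCC", pos_a = 1, pos_b = 4,
                              wt_bp = "GC", mut_bp = "CG"),
                   csv, row.names = FALSE)
  rec <- read_known_coms(csv)[[1]]
  expect_identical(com_rri_rank(rec, params), 2L)
  # rank found within n suboptimals is found at any larger budget
  expect_identical(com_rri_rank(rec, params, max_subopt = 50L), 2L)
  # and NA when the budget is too small or the pair is never realized
  expect_identical(com_rri_rank(rec, params, max_subopt = 1L), NA_integer_)
})

test_that("energy profiling builds the background from the remaining GC pairs", {
  path <- make_table(6, seed = 33)
  records <- read_known_coms(path)
  prof <- energy_profile(records, params)
  per <- prof$per_candidate
  expect_identical(sum(per$is_known), 6L)
  # per record: k GC pairs in the MFE, one being the known CoM
  for (r in records) {
    mfe <- duplex_mfe(r$seq_a, r$seq_b, params)
    k <- sum(is_pairable(mfe$pairs$nt_a, mfe$pairs$nt_b) &
               mfe$pairs$nt_a %in% c("G", "C") &
               mfe$pairs$nt_b %in% c("G", "C"))
    expect_identical(sum(per$pair_id == r$pair_id & !per$is_known), k - 1L)
  }
  expect_true(all(c("d_wm_ww", "d_mw_ww", "d_mm_ww", "d_wm_mm",
                    "d_mw_mm") %in% names(per)))
  expect_equal(per$d_wm_ww, per$mfe_wm - per$mfe_ww, tolerance = 1e-12)
  expect_identical(nrow(prof$welch), 4L)
  expect_identical(nrow(prof$paired), 10L)
})

test_that("profile t-tests agree with direct formula evaluation", {
  path <- make_table(6, seed = 34)
  records <- read_known_coms(path)
  prof <- energy_profile(records, params)
  per <- prof$per_candidate
  known <- per[per$is_known, ]; bg <- per[!per$is_known, ]
  for (cmb in c("mfe_ww", "mfe_wm", "mfe_mw", "mfe_mm")) {
    want <- welch_p_direct(known[[cmb]], bg[[cmb]])
    got <- prof$welch$p_value[prof$welch$combination == sub("mfe_", "", cmb)]
    expect_equal(got, want, tolerance = 1e-10)
  }
  for (g in c("known", "background")) {
    d <- if (g == "known") known else bg
    for (cl in c("d_wm_ww", "d_mm_ww")) {
      got <- prof$paired$p_value[prof$paired$group == g &
                                   prof$paired$column == cl]
      if (sd(d[[cl]]) == 0) {
        expect_true(is.na(got))
        expect_equal(mean(d[[cl]]),
                     prof$paired$mean_diff[prof$paired$group == g &
                                             prof$paired$column == cl])
      } else {
        expect_equal(got, paired_p_direct(d[[cl]]), tolerance = 1e-10)
      }
    }
  }
})

test_that("degenerate all-identical energy columns yield zero differences", {
  # identity-mutation records are test-only degenerates: build directly
  per_diff_zero <- data.frame(x = rep(-5, 4))
  expect_equal(sd(per_diff_zero$x), 0)
  # the profiling path flags the p-value NA rather than inventing one
  path <- make_table(3, seed = 35)
  records <- read_known_coms(path)
  prof <- energy_profile(records, params)
  expect_true(all(is.na(prof$welch$p_value) |
                    (prof$welch$p_value >= 0 & prof$welch$p_value <= 1)))
})

test_that("alpha/beta sweep counts are monotone and flag failing known CoMs", {
  path <- make_table(5, seed = 36)
  records <- read_known_coms(path)
  sw <- alpha_beta_sweep(records, alpha_grid = c(0, 1, 2, 4, 12),
                         beta_grid = c(0, 1, 2, 4, 12), params)
  cells <- sw$cells
  for (id in unique(cells$pair_id)) {
    for (b in unique(cells$beta)) {
      d <- cells[cells$pair_id == id & cells$beta == b, ]
      d <- d[order(d$alpha), ]
      cnt <- ifelse(d$known_valid, d$count, 0L)
      expect_true(all(diff(cnt) <= 0L))
      # validity is monotone too: once invalid, stays invalid
      expect_true(all(diff(as.integer(d$known_valid)) <= 0L))
    }
    for (a in unique(cells$alpha)) {
      d <- cells[cells$pair_id == id & cells$alpha == a, ]
      d <- d[order(d$beta), ]
      cnt <- ifelse(d$known_valid, d$count, 0L)
      expect_true(all(diff(cnt) <= 0L))
    }
  }
  # at extreme thresholds every known CoM fails the E constraints: breaking
  # one base pair can destabilize by at most two stacking terms plus a loop
  extreme <- sw$summary[sw$summary$alpha == 12 & sw$summary$beta == 12, ]
  expect_identical(extreme$n_known_invalid, length(records))
  expect_identical(sw$summary$n_records,
                   rep(length(records), nrow(sw$summary)))
})

test_that("classifier/sorter comparison prunes but never demotes a passing CoM", {
  path <- make_table(5, seed = 37)
  records <- read_known_coms(path)
  configs <- list(
    sort_only = ranking_config(classifier_chain = character(0)),
    with_E = ranking_config(classifier_chain = "E"),
    with_E_dup = ranking_config(classifier_chain = "E"),
    full = ranking_config())
  cm <- ranking_comparison(records, configs, params)
  cells <- cm$cells
  # identical configurations give identical outputs
  a <- cells[cells$config == "with_E", c("pair_id", "count", "known_valid")]
  b <- cells[cells$config == "with_E_dup",
             c("pair_id", "count", "known_valid")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  # empty chain: count equals the known CoM's minDeltaE rank
  for (r in records) {
    res <- rank_coms(r$seq_a, r$seq_b,
                     ranking_config(classifier_chain = character(0)))
    t <- res$table
    ki <- which(t$pos_a == r$coms$pos_a[1] & t$pos_b == r$coms$pos_b[1] &
                  t$mut_a == r$coms$mut_a[1] & t$mut_b == r$coms$mut_b[1])
    want <- if (length(ki) == 1L) t$rank[ki] else NA_integer_
    got <- cells$count[cells$config == "sort_only" &
                         cells$pair_id == r$pair_id]
    expect_identical(got, want)
  }
  # adding E to the chain never increases the count when the CoM passes E
  joined <- merge(cells[cells$config == "sort_only", ],
                  cells[cells$config == "with_E", ], by = "pair_id")
  ok <- joined$known_valid.y
  expect_true(all(joined$count.y[ok] <= joined$count.x[ok]))
})
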