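params <- energy_parameters()

quad <- function(ww, wm, mw, mm) c(ww = ww, wm = wm, mw = mw, mm = mm)

test_that("E classifier reproduces the threshold inequalities", {
  # -10 + 2 < min(-6.5, -7) and -9 + 1 < -7
  expect_true(e_classifier(quad(-10, -7, -6.5, -9), alpha = 2, beta = 1))
  # -10 + 2 < min(-9.5, -8.5) is false
  r <- e_classifier(quad(-10, -8.5, -9.5, -9), alpha = 2, beta = 1)
  expect_false(as.logical(r))
  expect_identical(attr(r, "reason"), "alpha_violated")
  # wildtype-only interaction absent (encoded 0) fails the below-zero check
  r <- e_classifier(quad(0, -7, -6.5, -9), alpha = 2, beta = 1)
  expect_false(as.logical(r))
  expect_identical(attr(r, "reason"), "ww_not_negative")
  r <- e_classifier(quad(-10, -7, -6.5, 0), alpha = 2, beta = 1)
  expect_identical(attr(r, "reason"), "mm_not_negative")
  # strict inequality: equality does not pass
  expect_false(e_classifier(quad(-10, -8, -8, -10), alpha = 2, beta = 2))
  expect_error(e_classifier(quad(-10, -7, -6, -9), alpha = -1), "alpha")
})

test_that("minDeltaE is min(mixed) - max(pure), with none-flags entering as 0", {
  expect_equal(min_delta_e(quad(-10, -7, -6, -9)), 2)
  expect_equal(min_delta_e(quad(-5, -5, -5, -5)), 0)
  # wm none-flagged (0): min(-4, 0) - max(-10, -9) = 5
  expect_equal(min_delta_e(quad(-10, 0, -4, -9)), 5)
})

test_that("classifier formulas match direct evaluation on a random grid", {
  set.seed(7)
  n <- 1200
  g <- data.frame(ww = round(runif(n, -15, 2), 2),
                  wm = round(runif(n, -15, 2), 2),
                  mw = round(runif(n, -15, 2), 2),
                  mm = round(runif(n, -15, 2), 2),
                  alpha = sample(c(0, 0.5, 1, 2, 3), n, TRUE),
                  beta = sample(c(0, 0.5, 1, 2, 3), n, TRUE))
  # none-flag cases: absent interactions are encoded as exactly 0
  flag <- sample(n, n %/% 5)
  g$wm[flag] <- 0
  g$mw[sample(n, n %/% 5)] <- 0
  for (k in seq_len(n)) {
    e <- quad(g$ww[k], g$wm[k], g$mw[k], g$mm[k])
    worst <- min(e[["mw"]], e[["wm"]])
    want_pass <- (e[["ww"]] < 0) && (e[["mm"]] < 0) &&
      (e[["ww"]] + g$alpha[k] < worst) && (e[["mm"]] + g$beta[k] < worst)
    expect_identical(as.logical(e_classifier(e, g$alpha[k], g$beta[k])),
                     want_pass)
    expect_equal(min_delta_e(e), worst - max(e[["ww"]], e[["mm"]]))
  }
})

test_that("the E-valid set shrinks monotonically in alpha and beta", {
  set.seed(8)
  n <- 300
  g <- data.frame(ww = runif(n, -15, 0), wm = runif(n, -15, 0),
                  mw = runif(n, -15, 0), mm = runif(n, -15, 0))
  valid_set <- function(alpha, beta) {
    which(vapply(seq_len(n), function(k) {
      as.logical(e_classifier(quad(g$ww[k], g$wm[k], g$mw[k], g$mm[k]),
                              alpha, beta))
    }, logical(1)))
  }
  grid <- c(0, 0.5, 1, 2, 3, 5)
  for (i in seq_along(grid)[-1]) {
    expect_true(all(valid_set(grid[i], 1) %in% valid_set(grid[i - 1], 1)))
    expect_true(all(valid_set(1, grid[i]) %in% valid_set(1, grid[i - 1])))
  }
})

test_that("combination evaluation mutates the right sequence states", {
  fx <- tiny_fixture(seed = 11)
  pred <- builtin_predictor(params)
  p <- fx$pairs
  mid <- ceiling(nrow(p) / 2)
  en <- evaluate_combinations(fx$seq_a, fx$seq_b, p$pos_a[mid],
                              p$pos_b[mid], p$nt_b[mid], p$nt_a[mid], pred)
  # ww equals the wildtype-only MFE, independent of the candidate
  ww <- duplex_mfe(fx$seq_a, fx$seq_b, params)
  expect_equal(en$mfe[["ww"]], ww$e_total, tolerance = 1e-9)
  # the oracle agrees on each mutated combination (fixture is oracle-sized)
  sa_m <- apply_mutation(fx$seq_a, p$pos_a[mid], p$nt_b[mid])
  sb_m <- apply_mutation(fx$seq_b, p$pos_b[mid], p$nt_a[mid])
  for (combo in list(list("wm", fx$seq_a, sb_m), list("mw", sa_m, fx$seq_b),
                     list("mm", sa_m, sb_m))) {
    o <- brute_force_duplex_mfe(combo[[2]], combo[[3]], params)
    e_o <- if (is.null(o)) 0 else o$e_total
    expect_equal(en$mfe[[combo[[1]]]], e_o, tolerance = 1e-9)
  }
  # breaking one pair of the only site cannot stabilize mixed combinations
  expect_gte(en$mfe[["wm"]], en$mfe[["ww"]] - 1e-9)
  expect_gte(en$mfe[["mw"]], en$mfe[["ww"]] - 1e-9)
  # degenerate identity mutation: all four combinations coincide
  iden <- evaluate_combinations(fx$seq_a, fx$seq_b, p$pos_a[mid],
                                p$pos_b[mid], p$nt_a[mid], p$nt_b[mid],
                                pred)
  expect_true(all(abs(iden$mfe - iden$mfe[["ww"]]) < 1e-9))
  expect_equal(min_delta_e(iden), 0, tolerance = 1e-9)
  expect_false(e_classifier(iden, alpha = 0.5, beta = 0.5))
})

test_that("mfeCover demands the mutated base pair inside the mutant-only MFE", {
  fx <- tiny_fixture(seed = 12)
  p <- fx$pairs
  mid <- ceiling(nrow(p) / 2)
  en <- evaluate_combinations(fx$seq_a, fx$seq_b, p$pos_a[mid],
                              p$pos_b[mid], p$nt_b[mid], p$nt_a[mid],
                              builtin_predictor(params))
  expect_true(mfe_cover(p$pos_a[mid], p$pos_b[mid], en))
  # absent mm interaction: not covered
  en_none <- en
  en_none$interactions$mm <- NULL
  expect_false(mfe_cover(p$pos_a[mid], p$pos_b[mid], en_none))
  # mm interaction spanning the positions without pairing them together
  other <- en$interactions$mm
  k <- which(other$pairs$pos_a == p$pos_a[mid])
  other$pairs <- other$pairs[-k, , drop = FALSE]
  en_other <- en
  en_other$interactions$mm <- other
  expect_false(mfe_cover(p$pos_a[mid], p$pos_b[mid], en_other))
})

test_that("ranking orders by stratum, then minDeltaE, then position", {
  base <- data.frame(
    pos_a = c(5L, 3L, 8L, 3L), pos_b = c(20L, 22L, 17L, 22L),
    mut_a = c("C", "C", "G", "U"), mut_b = c("G", "G", "C", "A"),
    mfe_cover_pass = c(TRUE, TRUE, FALSE, TRUE),
    e_pass = c(TRUE, FALSE, TRUE, TRUE),
    min_delta_e = c(1.5, 3.0, 9.9, 1.5), stringsAsFactors = FALSE)
  ranked <- rank_candidates(base, ranking_config())
  # full-pass candidates first; prefix semantics deny credit for E after a
  # failed mfeCover
  expect_identical(ranked$stratum[ranked$pos_a == 8L], 0L)
  expect_identical(ranked$rank, 1:4)
  expect_identical(ranked$pos_a, c(3L, 5L, 3L, 8L))
  expect_identical(ranked$mut_a, c("U", "C", "C", "G"))
  # within equal stratum minDeltaE never increases with rank
  for (s in unique(ranked$stratum)) {
    d <- ranked$min_delta_e[ranked$stratum == s]
    expect_true(all(diff(d) <= 1e-9))
  }
  # ties on stratum and minDeltaE break by position then mutant pair
  tied <- base[c(1, 1), ]
  tied$mut_a <- c("U", "C"); tied$mut_b <- c("A", "G")
  r2 <- rank_candidates(tied, ranking_config())
  expect_identical(r2$mut_a, c("C", "U"))
})

test_that("full ranking workflow finds the implanted site and is internally consistent", {
  fx <- generate_interacting_pair(fixture_spec(seed = 21))
  res <- rank_coms(fx$seq_a, fx$seq_b,
                   ranking_config(mutation_mode = "all"))
  t <- res$table
  expect_gt(nrow(t), 0L)
  expect_identical(sort(t$rank), seq_len(nrow(t)))
  # mfe_ww identical across candidates of one sequence pair
  expect_true(all(abs(t$mfe_ww - t$mfe_ww[1]) < 1e-9))
  expect_equal(t$mfe_ww[1], res$mfe$e_total, tolerance = 1e-9)
  # candidates lie inside the predicted interaction
  expect_true(all(t$pos_a >= res$mfe$start_a & t$pos_a <= res$mfe$end_a))
})

test_that("ranked CSV output round-trips and formats as specified", {
  fx <- generate_interacting_pair(fixture_spec(seed = 22))
  res <- rank_coms(fx$seq_a, fx$seq_b)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, path)
  lines <- readLines(path)
  expect_identical(length(lines), nrow(res$table) + 1L)
  back <- read_results_csv(path)
  expect_identical(back$rank, res$table$rank)
  expect_identical(back$pos_a, res$table$pos_a)
  expect_equal(back$minDeltaE, round(res$table$min_delta_e, 2),
               tolerance = 1e-9)
  expect_identical(back$mfeCover, res$table$mfe_cover_pass)
  # empty table gives a header-only file
  empty <- rank_coms("AAAA", "AAAA")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(empty, p2)
  expect_identical(length(readLines(p2)), 1L)
})

test_that("the external-predictor adapter parses, validates and serves records", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "key,start_a,end_a,start_b,end_b,e_total,e_hybrid,ed_a,ed_b,bp_list",
    "ww,1,3,1,3,-4.5,-5.0,0.3,0.2,\"(1,3) (2,2) (3,1)\"",
    "mm:2:2:C:G,1,3,1,3,-4.0,-4.0,0,0,\"(1,3) (2,2) (3,1)\""), csv)
  ints <- parse_external_interactions(csv, "GGG", "CCC")
  expect_named(ints, c("ww", "mm:2:2:C:G"))
  expect_equal(ints$ww$e_total, -4.5)
  expect_identical(ints$ww$pairs$pos_a, 1:3)
  pred <- external_predictor(ints)
  expect_equal(pred("GGG", "CCC", list(combo = "ww"))$e_total, -4.5)
  expect_equal(pred("GGG", "CCC", list(combo = "mm", pos_a = 2, pos_b = 2,
                                       mut_a = "C", mut_b = "G"))$e_total,
               -4.0)
  expect_null(pred("GGG", "CCC", list(combo = "wm", pos_a = 2, pos_b = 2,
                                      mut_a = "C", mut_b = "G")))
  # validation: base pair outside the declared boundaries
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "key,start_a,end_a,start_b,end_b,e_total,e_hybrid,ed_a,ed_b,bp_list",
    "ww,1,2,1,3,-4.5,-4.5,0,0,\"(1,3) (2,2) (3,1)\""), bad)
  expect_error(parse_external_interactions(bad), "inconsistent")
  # header-only file parses to an empty list
  hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines("key,start_a,end_a,start_b,end_b,e_total,e_hybrid,ed_a,ed_b,bp_list",
             hdr)
  expect_length(parse_external_interactions(hdr), 0L)
})
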