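# shared helpers for the comrank test suite

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# validity checks on a reported interaction
expect_valid_interaction <- function(x, seq_a, seq_b,
                                     params = energy_parameters()) {
  p <- x$pairs
  expect_gt(nrow(p), 0L)
  ca <- strsplit(toupper(gsub("T", "U", as.character(seq_a))), "")[[1]]
  cb <- strsplit(toupper(gsub("T", "U", as.character(seq_b))), "")[[1]]
  expect_identical(p$nt_a, ca[p$pos_a])
  expect_identical(p$nt_b, cb[p$pos_b])
  expect_true(all(is_pairable(p$nt_a, p$nt_b)))
  if (nrow(p) > 1L) {
    expect_true(all(diff(p$pos_a) > 0))
    expect_true(all(diff(p$pos_b) < 0))
    expect_true(all(diff(p$pos_a) - 1L <= params$max_loop_side))
    expect_true(all(-diff(p$pos_b) - 1L <= params$max_loop_side))
  }
  expect_equal(x$e_total, x$e_hybrid + x$ed_a + x$ed_b, tolerance = 1e-9)
  # energy decomposition agrees with the standalone scorer
  sc <- interaction_energy(p$pos_a, p$pos_b, seq_a, seq_b, params)
  expect_equal(x$e_hybrid, sc$e_hybrid, tolerance = 1e-9)
  invisible(x)
}

# a tiny oracle-scale fixture: perfect GC-rich implanted site
tiny_fixture <- function(seed, site_length = 6L, flank = 3L) {
  generate_interacting_pair(fixture_spec(
    site_length = site_length, gc_fraction = 1, flank_length_a = flank,
    flank_length_b = flank, wobble_fraction = 0, seed = seed))
}

# direct-formula Welch p-value (Satterthwaite df), the textbook oracle
welch_p_direct <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# direct-formula one-sample/paired p-value
paired_p_direct <- function(d) {
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  2 * pt(-abs(t), length(d) - 1)
}
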