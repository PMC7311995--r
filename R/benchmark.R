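# Benchmark harness over (sequence pair, known compensatory mutation)
# tables: mutation-type tallies, rank of the CoM-containing interaction,
# energy profiling with t-tests, alpha/beta sweeps, and classifier/sorter
# comparisons.

#' Read a known-CoM benchmark table
#'
#' Reads a CSV of known compensatory mutations. Required columns:
#' `pair_id`, `seq_a`, `seq_b` (inline residue strings, or paths to
#' single-record FASTA files when `fasta_dir` is given), `pos_a`, `pos_b`
#' (1-based positions of the mutated base pair), `wt_bp`, `mut_bp`
#' (two-letter nucleotide pairs, first letter = sequence A). Multi-pair
#' CoMs use one row per base pair sharing a `pair_id`.
#'
#' @param path CSV path.
#' @param fasta_dir Optional directory against which `seq_a`/`seq_b`
#'   entries that are not residue strings are resolved as FASTA files.
#' @return List of records, each a list with `pair_id`, `seq_a`, `seq_b`
#'   ([rna_seq]) and `coms` (data frame `pos_a`, `pos_b`, `wt_a`, `wt_b`,
#'   `mut_a`, `mut_b`).
#' @export
read_known_coms <- function(path, fasta_dir = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "seq_a", "seq_b", "pos_a", "pos_b", "wt_bp",
            "mut_bp")
  if (!all(need %in% names(tab))) {
    stop(sprintf("known-CoM table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  as_seq <- function(x, id) {
    if (grepl("^[ACGUTacgut]+$", x)) return(rna_seq(x, id = id))
    p <- if (is.null(fasta_dir)) x else file.path(fasta_dir, x)
    read_fasta(p)[[1L]]
  }
  split_rows <- split(seq_len(nrow(tab)), tab$pair_id)
  # preserve file order of first occurrence
  split_rows <- split_rows[unique(tab$pair_id)]
  lapply(names(split_rows), function(id) {
    rows <- tab[split_rows[[id]], , drop = FALSE]
    seq_a <- as_seq(rows$seq_a[1L], paste0(id, "_A"))
    seq_b <- as_seq(rows$seq_b[1L], paste0(id, "_B"))
    coms <- data.frame(
      pos_a = as.integer(rows$pos_a), pos_b = as.integer(rows$pos_b),
      wt_a = substr(rows$wt_bp, 1, 1), wt_b = substr(rows$wt_bp, 2, 2),
      mut_a = substr(rows$mut_bp, 1, 1), mut_b = substr(rows$mut_bp, 2, 2),
      stringsAsFactors = FALSE)
    ca <- seq_chars(seq_a); cb <- seq_chars(seq_b)
    for (k in seq_len(nrow(coms))) {
      if (coms$pos_a[k] < 1L || coms$pos_a[k] > length(ca) ||
          coms$pos_b[k] < 1L || coms$pos_b[k] > length(cb)) {
        stop(sprintf("%s: CoM position out of range", id), call. = FALSE)
      }
      if (ca[coms$pos_a[k]] != coms$wt_a[k] ||
          cb[coms$pos_b[k]] != coms$wt_b[k]) {
        stop(sprintf("%s: wildtype pair %s%s does not match the sequences",
                     id, coms$wt_a[k], coms$wt_b[k]), call. = FALSE)
      }
      if (!is_pairable(coms$wt_a[k], coms$wt_b[k]) ||
          !is_pairable(coms$mut_a[k], coms$mut_b[k]) ||
          is_pairable(coms$mut_a[k], coms$wt_b[k]) ||
          is_pairable(coms$wt_a[k], coms$mut_b[k])) {
        stop(sprintf("%s: CoM %s%s->%s%s violates pairing/compatibility rules",
                     id, coms$wt_a[k], coms$wt_b[k], coms$mut_a[k],
                     coms$mut_b[k]), call. = FALSE)
      }
    }
    list(pair_id = id, seq_a = seq_a, seq_b = seq_b, coms = coms)
  })
}

#' Lex-sorted mutation-type class
#'
#' Collapses a wildtype/mutant base-pair combination into its orientation-
#' free class label: the two wildtype letters lex-sorted followed by the
#' two mutant letters lex-sorted. `"AUCG"` thus covers an AU or UA
#' wildtype pair mutated to CG or GC.
#'
#' @param wt_bp,mut_bp Two-letter base-pair strings (first letter =
#'   sequence A); vectors recycle.
#' @return Character vector of 4-letter class labels.
#' @export
mutation_type_class <- function(wt_bp, mut_bp) {
  n <- max(length(wt_bp), length(mut_bp))
  wt_bp <- rep_len(wt_bp, n); mut_bp <- rep_len(mut_bp, n)
  paste0(lex_bp(substr(wt_bp, 1, 1), substr(wt_bp, 2, 2)),
         lex_bp(substr(mut_bp, 1, 1), substr(mut_bp, 2, 2)))
}

#' Tally mutation-type classes of a known-CoM table
#'
#' @param records Output of [read_known_coms].
#' @return Data frame `class`, `count`, sorted by decreasing count.
#' @export
mutation_type_tally <- function(records) {
  classes <- unlist(lapply(records, function(r) {
    mutation_type_class(paste0(r$coms$wt_a, r$coms$wt_b),
                        paste0(r$coms$mut_a, r$coms$mut_b))
  }))
  tab <- table(classes)
  out <- data.frame(class = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$class), , drop = FALSE]
}

#' Rank of the interaction containing a known CoM
#'
#' Enumerates the energy-sorted, boundary-unique suboptimal interactions of
#' a record's sequence pair and returns the 1-based index of the first
#' interaction containing at least one of the record's CoM base pairs, or
#' `NA` if none of the first `max_subopt` interactions does.
#'
#' @param record One record from [read_known_coms].
#' @param params [energy_parameters].
#' @param acc Accessibility provider.
#' @param max_subopt Number of suboptimal interactions examined.
#' @return Integer rank or `NA_integer_`.
#' @export
com_rri_rank <- function(record, params = energy_parameters(),
                         acc = acc_none(), max_subopt = 10L) {
  stopifnot(max_subopt >= 1L)
  subs <- enumerate_suboptimals(record$seq_a, record$seq_b, params, acc,
                                max_count = max_subopt)
  for (r in seq_along(subs)) {
    for (k in seq_len(nrow(record$coms))) {
      if (interaction_has_pair(subs[[r]], record$coms$pos_a[k],
                               record$coms$pos_b[k])) {
        return(r)
      }
    }
  }
  NA_integer_
}

# Evaluate all GC-flip candidates of a record's MFE interaction, marking
# the known CoM; shared by the profiling/sweep/comparison analyses.
gc_flip_energies <- function(record, params, acc, predictor = NULL) {
  if (is.null(predictor)) predictor <- builtin_predictor(params, acc)
  mfe <- duplex_mfe(record$seq_a, record$seq_b, params, acc)
  if (is.null(mfe)) return(NULL)
  p <- mfe$pairs
  gc <- p[lex_bp(p$nt_a, p$nt_b) == "CG", , drop = FALSE]
  if (nrow(gc) == 0L) return(NULL)
  rows <- lapply(seq_len(nrow(gc)), function(k) {
    en <- evaluate_combinations(record$seq_a, record$seq_b, gc$pos_a[k],
                                gc$pos_b[k], gc$nt_b[k], gc$nt_a[k],
                                predictor, ww = mfe)
    data.frame(
      pair_id = record$pair_id, pos_a = gc$pos_a[k], pos_b = gc$pos_b[k],
      wt_bp = paste0(gc$nt_a[k], gc$nt_b[k]),
      mut_bp = paste0(gc$nt_b[k], gc$nt_a[k]),
      is_known = any(record$coms$pos_a == gc$pos_a[k] &
                       record$coms$pos_b == gc$pos_b[k]),
      mfe_ww = en$mfe[["ww"]], mfe_wm = en$mfe[["wm"]],
      mfe_mw = en$mfe[["mw"]], mfe_mm = en$mfe[["mm"]],
      mm_none = en$none[["mm"]],
      mfe_cover_pass = mfe_cover(gc$pos_a[k], gc$pos_b[k], en),
      min_delta_e = min_delta_e(en), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Energy profiling of known CoMs against a background model
#'
#' For each record, treats all GC base pairs of the wildtype MFE
#' interaction as flipped (CGCG-class) compensatory mutations. The known
#' CoM forms the "known" group and the remaining GC flips the background
#' group. Per candidate the four combination MFEs, the five pairwise
#' differences (`wm-ww`, `mw-ww`, `mm-ww`, `wm-mm`, `mw-mm`) and minDeltaE
#' are reported. Group comparisons use a Welch two-sample t-test
#' (two-tailed, unequal variance, unpaired: known vs background per
#' combination) and paired t-tests for each difference column within each
#' group; p-values are `NA` when a group has fewer than 2 observations.
#'
#' @param records Output of [read_known_coms]; records whose known CoM is
#'   not a GC pair of the MFE interaction still contribute background
#'   flips.
#' @inheritParams com_rri_rank
#' @return List of class `com_energy_profile`: `per_candidate` (long data
#'   frame), `welch` (combination, p_value, group sizes), `paired` (group,
#'   column, mean difference, p_value).
#' @export
energy_profile <- function(records, params = energy_parameters(),
                           acc = acc_none()) {
  per <- do.call(rbind, Filter(Negate(is.null), lapply(records, function(r) {
    gc_flip_energies(r, params, acc)
  })))
  if (is.null(per) || nrow(per) == 0L) {
    stop("no GC flip candidates found in any record", call. = FALSE)
  }
  per$d_wm_ww <- per$mfe_wm - per$mfe_ww
  per$d_mw_ww <- per$mfe_mw - per$mfe_ww
  per$d_mm_ww <- per$mfe_mm - per$mfe_ww
  per$d_wm_mm <- per$mfe_wm - per$mfe_mm
  per$d_mw_mm <- per$mfe_mw - per$mfe_mm
  combos <- c("mfe_ww", "mfe_wm", "mfe_mw", "mfe_mm")
  known <- per[per$is_known, , drop = FALSE]
  bg <- per[!per$is_known, , drop = FALSE]
  welch_p <- function(col) {
    x <- known[[col]]; y <- bg[[col]]
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(NA_real_)
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }
  welch <- data.frame(combination = sub("mfe_", "", combos),
                      p_value = vapply(combos, welch_p, numeric(1)),
                      n_known = nrow(known), n_background = nrow(bg),
                      stringsAsFactors = FALSE)
  diffs <- c("d_wm_ww", "d_mw_ww", "d_mm_ww", "d_wm_mm", "d_mw_mm")
  paired <- do.call(rbind, lapply(c("known", "background"), function(g) {
    d <- if (g == "known") known else bg
    data.frame(group = g, column = diffs,
               mean_diff = vapply(diffs, function(cl) mean(d[[cl]]),
                                  numeric(1)),
               p_value = vapply(diffs, function(cl) {
                 v <- d[[cl]]
                 if (length(v) < 2L || stats::sd(v) == 0) return(NA_real_)
                 stats::t.test(v)$p.value
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(welch) <- rownames(paired) <- NULL
  structure(list(per_candidate = per, welch = welch, paired = paired),
            class = "com_energy_profile")
}

#' @export
print.com_energy_profile <- function(x, ...) {
  cat(sprintf("<com_energy_profile> %d candidates (%d known, %d background)\n",
              nrow(x$per_candidate), sum(x$per_candidate$is_known),
              sum(!x$per_candidate$is_known)))
  cat("Welch t-tests (known vs background):\n")
  print(x$welch, row.names = FALSE)
  invisible(x)
}

# Rank the GC-flip candidates of one record under a given E(alpha, beta)
# chain and locate the known CoM. Returns NULL if the record has no GC
# flips, and known_found = FALSE if the known CoM is not among them.
sweep_record_counts <- function(flips, alpha, beta, chain = "E") {
  flips$e_pass <- vapply(seq_len(nrow(flips)), function(k) {
    as.logical(e_classifier(c(ww = flips$mfe_ww[k], wm = flips$mfe_wm[k],
                              mw = flips$mfe_mw[k], mm = flips$mfe_mm[k]),
                            alpha, beta))
  }, logical(1))
  cfg <- ranking_config(alpha = alpha, beta = beta,
                        classifier_chain = chain)
  flips$mut_a <- substr(flips$mut_bp, 1, 1)
  flips$mut_b <- substr(flips$mut_bp, 2, 2)
  ranked <- rank_candidates(flips, cfg)
  ki <- which(ranked$is_known)
  full <- length(chain)
  valid <- ranked$stratum == full
  if (length(ki) == 0L) {
    return(list(known_found = FALSE, known_valid = FALSE,
                count = NA_integer_))
  }
  ki <- ki[1L]
  if (!valid[ki]) {
    return(list(known_found = TRUE, known_valid = FALSE,
                count = NA_integer_))
  }
  list(known_found = TRUE, known_valid = TRUE,
       count = sum(valid & ranked$rank <= ranked$rank[ki]))
}

#' Alpha/beta threshold sweep
#'
#' For every grid combination of `alpha` and `beta`, ranks each record's
#' GC-flip candidates (generation restricted to flips of the MFE
#' interaction's GC base pairs) under the E classifier with those
#' thresholds, sorted by minDeltaE, and counts the E-valid candidates
#' ranked not worse than the record's known CoM. Records whose known CoM
#' fails the E constraints (or is not among the generated flips) are
#' flagged and excluded from the grid-cell mean.
#'
#' @param records Output of [read_known_coms].
#' @param alpha_grid,beta_grid Numeric grids (non-empty).
#' @inheritParams com_rri_rank
#' @return List of class `com_sweep`: `cells` (long data frame: `alpha`,
#'   `beta`, `pair_id`, `count`, `known_valid`, `known_found`) and
#'   `summary` (`alpha`, `beta`, `mean_count`, `n_known_invalid`,
#'   `n_records`).
#' @export
alpha_beta_sweep <- function(records, alpha_grid = 1:5, beta_grid = 1:5,
                             params = energy_parameters(),
                             acc = acc_none()) {
  stopifnot(length(alpha_grid) >= 1L, length(beta_grid) >= 1L)
  flips_by_record <- lapply(records, function(r) {
    gc_flip_energies(r, params, acc)
  })
  names(flips_by_record) <- vapply(records, `[[`, character(1), "pair_id")
  cells <- list()
  for (a in alpha_grid) {
    for (b in beta_grid) {
      for (id in names(flips_by_record)) {
        flips <- flips_by_record[[id]]
        if (is.null(flips)) {
          cells[[length(cells) + 1L]] <- data.frame(
            alpha = a, beta = b, pair_id = id, count = NA_integer_,
            known_valid = FALSE, known_found = FALSE,
            stringsAsFactors = FALSE)
          next
        }
        res <- sweep_record_counts(flips, a, b)
        cells[[length(cells) + 1L]] <- data.frame(
          alpha = a, beta = b, pair_id = id, count = res$count,
          known_valid = res$known_valid, known_found = res$known_found,
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)
  agg <- do.call(rbind, lapply(split(cells, list(cells$alpha, cells$beta),
                                     drop = TRUE), function(d) {
    data.frame(alpha = d$alpha[1L], beta = d$beta[1L],
               mean_count = if (any(d$known_valid))
                 mean(d$count[d$known_valid]) else NA_real_,
               n_known_invalid = sum(!d$known_valid),
               n_records = nrow(d), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$alpha, agg$beta), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(cells = cells, summary = agg), class = "com_sweep")
}

#' @export
print.com_sweep <- function(x, ...) {
  cat(sprintf("<com_sweep> %d grid cells x records\n", nrow(x$cells)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Classifier/sorter ranking comparison
#'
#' Evaluates the full ranking workflow of each configuration on each
#' record: candidates are generated per the configuration, ranked, and the
#' number of fully-valid candidates (passing the whole classifier chain)
#' ranked not worse than the known CoM is reported. Records whose known
#' CoM is filtered out during generation or fails the chain count as
#' failures for that configuration.
#'
#' @param records Output of [read_known_coms].
#' @param configs Named list of [ranking_config] objects (names label the
#'   output).
#' @inheritParams com_rri_rank
#' @return List of class `com_config_comparison`: `cells` (`config`,
#'   `pair_id`, `count`, `known_valid`, `known_found`) and `summary`
#'   (`config`, `mean_count`, `n_known_invalid`, `n_records`).
#' @export
ranking_comparison <- function(records, configs,
                               params = energy_parameters(),
                               acc = acc_none()) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  if (is.null(names(configs)) || any(names(configs) == "")) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  cells <- list()
  for (cn in names(configs)) {
    cfg <- configs[[cn]]
    stopifnot(inherits(cfg, "ranking_config"))
    for (r in records) {
      res <- rank_coms(r$seq_a, r$seq_b, cfg, params, acc)
      t <- res$table
      full <- length(cfg$classifier_chain)
      row <- data.frame(config = cn, pair_id = r$pair_id,
                        count = NA_integer_, known_valid = FALSE,
                        known_found = FALSE, stringsAsFactors = FALSE)
      if (nrow(t) > 0L) {
        ki <- which(t$pos_a == r$coms$pos_a[1L] &
                      t$pos_b == r$coms$pos_b[1L] &
                      t$mut_a == r$coms$mut_a[1L] &
                      t$mut_b == r$coms$mut_b[1L])
        if (length(ki) == 1L) {
          row$known_found <- TRUE
          if (t$stratum[ki] == full) {
            row$known_valid <- TRUE
            row$count <- sum(t$stratum == full & t$rank <= t$rank[ki])
          }
        }
      }
      cells[[length(cells) + 1L]] <- row
    }
  }
  cells <- do.call(rbind, cells)
  agg <- do.call(rbind, lapply(split(cells, cells$config), function(d) {
    data.frame(config = d$config[1L],
               mean_count = if (any(d$known_valid))
                 mean(d$count[d$known_valid]) else NA_real_,
               n_known_invalid = sum(!d$known_valid),
               n_records = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(cells = cells, summary = agg),
            class = "com_config_comparison")
}

#' @export
print.com_config_comparison <- function(x, ...) {
  cat("<com_config_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
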