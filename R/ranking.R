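# Candidate evaluation across the four wildtype/mutant combinations, the
# hierarchical classifier chain (mfeCover, E), minDeltaE sorting, and the
# ranked-output container.

#' Ranking configuration
#'
#' Bundles all tunable settings of the ranking workflow: the E-classifier
#' thresholds `alpha` and `beta` (kcal/mol), the ordered classifier chain,
#' the sorting function, the mutation mode, candidate filters, and the
#' base-pair collection mode.
#'
#' Defaults follow the benchmark-backed recommendation: classifier chain
#' `mfeCover` then `E` with `alpha = 2`, `beta = 1`, sorted by `minDeltaE`,
#' nucleotide-flip mutations from the MFE interaction's base pairs.
#'
#' @param alpha,beta Non-negative energy thresholds (kcal/mol) of the E
#'   classifier.
#' @param classifier_chain Ordered unique subset of
#'   `c("mfeCover", "E")` (may be empty).
#' @param sorter Currently `"minDeltaE"`.
#' @param mutation_mode `"flip"` or `"all"`.
#' @param filters A [candidate_filters] object.
#' @param collection `"mfe"` or `"mfe_subopt"`.
#' @param max_subopt Suboptimal interactions examined in `"mfe_subopt"`
#'   collection mode.
#' @return An object of class `ranking_config`.
#' @export
ranking_config <- function(alpha = 2, beta = 1,
                           classifier_chain = c("mfeCover", "E"),
                           sorter = "minDeltaE",
                           mutation_mode = c("flip", "all"),
                           filters = candidate_filters(),
                           collection = c("mfe", "mfe_subopt"),
                           max_subopt = 20L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0)
  classifier_chain <- as.character(classifier_chain)
  if (anyDuplicated(classifier_chain)) {
    stop("classifier_chain entries must be unique", call. = FALSE)
  }
  bad <- setdiff(classifier_chain, c("mfeCover", "E"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown classifier: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  sorter <- match.arg(sorter, "minDeltaE")
  structure(list(alpha = alpha, beta = beta,
                 classifier_chain = classifier_chain, sorter = sorter,
                 mutation_mode = match.arg(mutation_mode),
                 filters = filters, collection = match.arg(collection),
                 max_subopt = as.integer(max_subopt)),
            class = "ranking_config")
}

#' Interaction predictors
#'
#' A predictor is the function the ranking workflow calls to obtain the MFE
#' interaction of a (possibly mutated) sequence combination. It receives
#' the two sequences plus a `meta` list (`combo` in `ww`/`wm`/`mw`/`mm` and,
#' for mutant combinations, the candidate identity `pos_a`, `pos_b`,
#' `mut_a`, `mut_b`) and returns an `rri_interaction` or `NULL`.
#'
#' `builtin_predictor()` wraps [duplex_mfe] with fixed parameters and
#' accessibility. `external_predictor()` serves precomputed interactions
#' from an adapter table (see [parse_external_interactions]), keyed by
#' `"ww"` for the wildtype combination and
#' `"<combo>:<pos_a>:<pos_b>:<mut_a>:<mut_b>"` for mutant combinations; a
#' missing key means no favourable interaction was predicted.
#'
#' @param params [energy_parameters].
#' @param acc Accessibility provider.
#' @param interactions Named list of `rri_interaction` records as returned
#'   by [parse_external_interactions].
#' @return A predictor function.
#' @name predictors
NULL

#' @rdname predictors
#' @export
builtin_predictor <- function(params = energy_parameters(),
                              acc = acc_none()) {
  force(params); force(acc)
  function(seq_a, seq_b, meta = list()) {
    duplex_mfe(seq_a, seq_b, params, acc)
  }
}

#' @rdname predictors
#' @export
external_predictor <- function(interactions) {
  stopifnot(is.list(interactions))
  force(interactions)
  function(seq_a, seq_b, meta = list()) {
    key <- if (identical(meta$combo, "ww") || is.null(meta$combo)) {
      "ww"
    } else {
      paste(meta$combo, meta$pos_a, meta$pos_b, meta$mut_a, meta$mut_b,
            sep = ":")
    }
    interactions[[key]]
  }
}

#' Evaluate the four wildtype/mutant sequence combinations
#'
#' Computes the predictor's MFE interaction for each of the four sequence
#' combinations of one compensatory-mutation candidate: `ww` (both
#' wildtype), `wm` (B mutated at `pos_b`), `mw` (A mutated at `pos_a`) and
#' `mm` (both mutated). An absent favourable interaction is encoded as
#' energy 0 with an explicit none-flag.
#'
#' @param seq_a,seq_b Wildtype sequences.
#' @param pos_a,pos_b Candidate base-pair positions (1-based).
#' @param mut_a,mut_b Mutant nucleotides.
#' @param predictor A predictor function (see [predictors]).
#' @param ww Optional precomputed `ww` interaction (it does not depend on
#'   the candidate, so callers evaluating many candidates compute it once).
#' @return List of class `combination_energies` with elements `mfe`
#'   (named numeric, `ww`/`wm`/`mw`/`mm`), `none` (named logical) and
#'   `interactions` (named list of `rri_interaction` or `NULL`).
#' @export
evaluate_combinations <- function(seq_a, seq_b, pos_a, pos_b, mut_a, mut_b,
                                  predictor = builtin_predictor(),
                                  ww = NULL) {
  seq_a <- as_rna_seq(seq_a, "A"); seq_b <- as_rna_seq(seq_b, "B")
  mut_seq_a <- apply_mutation(seq_a, pos_a, mut_a)
  mut_seq_b <- apply_mutation(seq_b, pos_b, mut_b)
  meta <- list(pos_a = pos_a, pos_b = pos_b, mut_a = mut_a, mut_b = mut_b)
  run <- function(sa, sb, combo) {
    m <- meta; m$combo <- combo
    tryCatch(predictor(sa, sb, m), error = function(e) {
      stop(sprintf("predictor failed for combination %s of candidate (%d, %d, %s%s): %s",
                   combo, pos_a, pos_b, mut_a, mut_b, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ints <- list(
    ww = if (is.null(ww)) run(seq_a, seq_b, "ww") else ww,
    wm = run(seq_a, mut_seq_b, "wm"),
    mw = run(mut_seq_a, seq_b, "mw"),
    mm = run(mut_seq_a, mut_seq_b, "mm")
  )
  none <- vapply(ints, is.null, logical(1))
  mfe <- vapply(ints, function(x) if (is.null(x)) 0 else x$e_total,
                numeric(1))
  structure(list(mfe = mfe, none = none, interactions = ints),
            class = "combination_energies")
}

#' mfeCover classifier
#'
#' Checks whether the compensatory mutation is covered by the mutant-only
#' (`mm`) MFE interaction: the mutated base pair `(pos_a, pos_b)` must be
#' present in the `mm` interaction. If not, the mutant-only interaction was
#' predicted in a different location (or the mutated positions pair with
#' other partners), or no favourable interaction exists at all -- either way
#' the double mutant is not expected to restore the probed base pair.
#'
#' @param pos_a,pos_b Candidate base-pair positions.
#' @param energies A `combination_energies` object.
#' @return Logical.
#' @export
mfe_cover <- function(pos_a, pos_b, energies) {
  mm <- energies$interactions$mm
  if (is.null(mm)) return(FALSE)
  interaction_has_pair(mm, pos_a, pos_b)
}

#' Energy-difference (E) classifier
#'
#' Requires the intended stability pattern of a verification experiment:
#' both single-sided wildtype-mutant combinations must be destabilized
#' relative to both wildtype-only and mutant-only interactions,
#' \deqn{MFE(ww) + \alpha < \min(MFE(mw), MFE(wm))}
#' \deqn{MFE(mm) + \beta < \min(MFE(mw), MFE(wm))}
#' with strict inequalities, and both `MFE(ww)` and `MFE(mm)` must be below
#' zero (a favourable interaction must exist for the wildtype and the
#' double mutant). Combinations without a favourable interaction enter the
#' arithmetic as 0, i.e. maximally destabilized.
#'
#' @param energies A `combination_energies` object (or a named numeric with
#'   entries `ww`, `wm`, `mw`, `mm`, taken as already none-encoded).
#' @param alpha,beta Non-negative thresholds, kcal/mol.
#' @return Logical with attribute `reason` (`"ok"`, `"ww_not_negative"`,
#'   `"mm_not_negative"`, `"alpha_violated"` or `"beta_violated"`; the
#'   first failed check is reported).
#' @export
e_classifier <- function(energies, alpha = 2, beta = 1) {
  stopifnot(alpha >= 0, beta >= 0)
  e <- if (inherits(energies, "combination_energies")) energies$mfe
       else energies
  stopifnot(all(c("ww", "wm", "mw", "mm") %in% names(e)))
  worst_mixed <- min(e[["mw"]], e[["wm"]])
  reason <- if (!(e[["ww"]] < 0)) "ww_not_negative"
    else if (!(e[["mm"]] < 0)) "mm_not_negative"
    else if (!(e[["ww"]] + alpha < worst_mixed)) "alpha_violated"
    else if (!(e[["mm"]] + beta < worst_mixed)) "beta_violated"
    else "ok"
  structure(reason == "ok", reason = reason)
}

#' minDeltaE sorting statistic
#'
#' The minimal MFE difference between the wildtype-mutant combinations and
#' the wildtype-only/mutant-only combinations:
#' \deqn{\min(MFE(mw), MFE(wm)) - \max(MFE(ww), MFE(mm))}
#' Larger values indicate a stronger, more symmetric destabilization of the
#' mixed combinations and hence a more discriminative verification signal.
#' Combinations without a favourable interaction enter as 0.
#'
#' @inheritParams e_classifier
#' @return Numeric, kcal/mol.
#' @export
min_delta_e <- function(energies) {
  e <- if (inherits(energies, "combination_energies")) energies$mfe
       else energies
  stopifnot(all(c("ww", "wm", "mw", "mm") %in% names(e)))
  min(e[["mw"]], e[["wm"]]) - max(e[["ww"]], e[["mm"]])
}

#' Rank evaluated candidates
#'
#' Orders evaluated candidates by the hierarchical ranking: the stratum --
#' the length of the longest prefix of the classifier chain whose
#' classifiers all pass (larger is better; a candidate failing the first
#' chain entry gets no credit for passing later ones) -- descending, then
#' the minDeltaE statistic descending, then `pos_a` ascending and the
#' mutant pair lexicographically for determinism. Ranks 1..N are assigned
#' in that order.
#'
#' @param evaluated Data frame with columns `pos_a`, `pos_b`, `mut_a`,
#'   `mut_b`, `mfe_cover_pass`, `e_pass`, `min_delta_e` (plus any others,
#'   carried through).
#' @param config A [ranking_config].
#' @return The data frame with added `stratum` and `rank` columns, ordered
#'   by rank.
#' @export
rank_candidates <- function(evaluated, config = ranking_config()) {
  stopifnot(inherits(config, "ranking_config"))
  if (nrow(evaluated) == 0L) {
    evaluated$stratum <- integer(0)
    evaluated$rank <- integer(0)
    return(evaluated)
  }
  pass_cols <- list(mfeCover = evaluated$mfe_cover_pass,
                    E = evaluated$e_pass)
  chain <- config$classifier_chain
  stratum <- rep(length(chain), nrow(evaluated))
  if (length(chain) > 0L) {
    for (k in seq_along(chain)) {
      failed_here <- !pass_cols[[chain[k]]] & stratum >= k
      stratum[failed_here] <- k - 1L
    }
  }
  evaluated$stratum <- as.integer(stratum)
  ord <- order(-evaluated$stratum, -evaluated$min_delta_e, evaluated$pos_a,
               evaluated$mut_a, evaluated$mut_b)
  evaluated <- evaluated[ord, , drop = FALSE]
  evaluated$rank <- seq_len(nrow(evaluated))
  rownames(evaluated) <- NULL
  evaluated
}

#' Generate, evaluate and rank compensatory-mutation candidates
#'
#' The main entry point: predicts the wildtype MFE interaction, generates
#' filtered compensatory-mutation candidates ([generate_candidates]),
#' evaluates each across the four wildtype/mutant sequence combinations
#' ([evaluate_combinations]), applies the classifier chain and minDeltaE
#' sorting, and returns the ranked table.
#'
#' @param seq_a,seq_b Sequences ([rna_seq], plain strings, or paths handled
#'   upstream).
#' @param config A [ranking_config].
#' @param params [energy_parameters] (used by the builtin predictor and for
#'   candidate generation).
#' @param acc Accessibility provider.
#' @param predictor Optional predictor function (see [predictors]);
#'   defaults to the builtin nearest-neighbor predictor with `params` and
#'   `acc`.
#' @return An object of class `com_ranking`: a list with `table` (the
#'   ranked candidate data frame), `mfe` (wildtype MFE interaction or
#'   `NULL`), `config`, `seq_a`, `seq_b`.
#' @examples
#' fx <- generate_interacting_pair(fixture_spec(site_length = 8,
#'                                              flank_length_a = 6,
#'                                              flank_length_b = 6,
#'                                              seed = 1))
#' res <- rank_coms(fx$seq_a, fx$seq_b)
#' head(as.data.frame(res))
#' @export
rank_coms <- function(seq_a, seq_b, config = ranking_config(),
                      params = energy_parameters(), acc = acc_none(),
                      predictor = NULL) {
  stopifnot(inherits(config, "ranking_config"))
  seq_a <- as_rna_seq(seq_a, "A"); seq_b <- as_rna_seq(seq_b, "B")
  if (is.null(predictor)) predictor <- builtin_predictor(params, acc)
  gen <- generate_candidates(seq_a, seq_b, params, acc,
                             mode = config$collection,
                             filters = config$filters,
                             mutation_mode = config$mutation_mode,
                             max_subopt = config$max_subopt)
  cand <- gen$candidates
  ww <- gen$mfe
  rows <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    en <- evaluate_combinations(seq_a, seq_b, cand$pos_a[k], cand$pos_b[k],
                                cand$mut_a[k], cand$mut_b[k], predictor,
                                ww = ww)
    ep <- e_classifier(en, config$alpha, config$beta)
    rows[[k]] <- data.frame(
      mfe_ww = en$mfe[["ww"]], mfe_wm = en$mfe[["wm"]],
      mfe_mw = en$mfe[["mw"]], mfe_mm = en$mfe[["mm"]],
      ww_none = en$none[["ww"]], wm_none = en$none[["wm"]],
      mw_none = en$none[["mw"]], mm_none = en$none[["mm"]],
      mfe_cover_pass = mfe_cover(cand$pos_a[k], cand$pos_b[k], en),
      e_pass = as.logical(ep), e_reason = attr(ep, "reason"),
      min_delta_e = min_delta_e(en), stringsAsFactors = FALSE)
  }
  evaluated <- if (length(rows) > 0L) cbind(cand, do.call(rbind, rows))
               else cbind(cand, data.frame(
                 mfe_ww = numeric(0), mfe_wm = numeric(0),
                 mfe_mw = numeric(0), mfe_mm = numeric(0),
                 ww_none = logical(0), wm_none = logical(0),
                 mw_none = logical(0), mm_none = logical(0),
                 mfe_cover_pass = logical(0), e_pass = logical(0),
                 e_reason = character(0), min_delta_e = numeric(0)))
  ranked <- rank_candidates(evaluated, config)
  structure(list(table = ranked, mfe = ww, config = config,
                 seq_a = seq_a, seq_b = seq_b),
            class = "com_ranking")
}

#' @export
print.com_ranking <- function(x, ...) {
  cat(sprintf("<com_ranking> %s vs %s: %d candidate(s)\n",
              x$seq_a$id, x$seq_b$id, nrow(x$table)))
  if (is.null(x$mfe)) {
    cat("  no favourable wildtype interaction\n")
    return(invisible(x))
  }
  cat(sprintf("  wildtype MFE %.2f kcal/mol, A[%d..%d] x B[%d..%d]\n",
              x$mfe$e_total, x$mfe$start_a, x$mfe$end_a, x$mfe$start_b,
              x$mfe$end_b))
  if (nrow(x$table) > 0L) {
    top <- utils::head(x$table, 5L)
    cat("  top candidates (rank, bp, mutation, minDeltaE):\n")
    for (k in seq_len(nrow(top))) {
      cat(sprintf("    %d: (%d,%d) %s%s->%s%s  minDeltaE %.2f%s%s\n",
                  top$rank[k], top$pos_a[k], top$pos_b[k], top$nt_a[k],
                  top$nt_b[k], top$mut_a[k], top$mut_b[k],
                  top$min_delta_e[k],
                  if (top$mfe_cover_pass[k]) " mfeCover" else "",
                  if (top$e_pass[k]) " E" else ""))
    }
  }
  invisible(x)
}

#' @export
summary.com_ranking <- function(object, ...) {
  t <- object$table
  cat(sprintf("Compensatory mutation ranking: %d candidate(s)\n", nrow(t)))
  cat(sprintf("  chain: %s; sorter: %s; alpha = %.2f, beta = %.2f\n",
              if (length(object$config$classifier_chain) > 0)
                paste(object$config$classifier_chain, collapse = " -> ")
              else "(none)",
              object$config$sorter, object$config$alpha,
              object$config$beta))
  if (nrow(t) > 0L) {
    cat(sprintf("  mfeCover pass: %d; E pass: %d; full-stratum: %d\n",
                sum(t$mfe_cover_pass), sum(t$e_pass),
                sum(t$stratum == length(object$config$classifier_chain))))
  }
  invisible(object)
}

#' @export
as.data.frame.com_ranking <- function(x, ...) x$table

#' Write a ranked candidate table as CSV
#'
#' Writes the user-facing result table (RFC-4180 quoting, header line, one
#' row per candidate in rank order). Coordinates are 1-based inclusive;
#' energies are printed with 2 decimals; absent favourable interactions
#' show their none-flag alongside the 0 energy.
#'
#' @param x A `com_ranking` object (or its `table` data frame).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  t <- if (inherits(x, "com_ranking")) x$table else x
  out <- data.frame(
    rank = t$rank,
    pos_a = t$pos_a, pos_b = t$pos_b,
    wt_bp = paste0(t$nt_a, t$nt_b),
    mut_bp = paste0(t$mut_a, t$mut_b),
    context = t$context,
    mfe_ww = sprintf("%.2f", t$mfe_ww), mfe_wm = sprintf("%.2f", t$mfe_wm),
    mfe_mw = sprintf("%.2f", t$mfe_mw), mfe_mm = sprintf("%.2f", t$mfe_mm),
    none_flags = paste0(ifelse(t$ww_none, "ww", ""),
                        ifelse(t$wm_none, " wm", ""),
                        ifelse(t$mw_none, " mw", ""),
                        ifelse(t$mm_none, " mm", "")),
    mfeCover = t$mfe_cover_pass,
    E_pass = t$e_pass,
    minDeltaE = sprintf("%.2f", t$min_delta_e),
    stringsAsFactors = FALSE)
  if (nrow(out) > 0L) out$none_flags <- trimws(out$none_flags)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a ranked candidate CSV
#'
#' Round-trip reader for files written by [write_results_csv].
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(none_flags = "character"))
}
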