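# Compensatory-mutation candidate generation: base-pair collection from
# predicted interactions, helix-context classification, filtering, and
# mutant-pair enumeration.

#' Helix context of a base pair within an interaction
#'
#' Classifies an inter-molecular base pair by its stacking neighborhood
#' inside a given interaction: `"stacked_both"` if both diagonal neighbors
#' `(pos_a - 1, pos_b + 1)` and `(pos_a + 1, pos_b - 1)` are also paired,
#' `"helix_end"` if exactly one is, and `"lonely"` if neither is. Lonely
#' pairs cannot stack on either side and typically contribute little
#' stability; helix-end pairs stack on one side only.
#'
#' @param interaction An `rri_interaction`.
#' @param pos_a,pos_b 1-based positions of a base pair that must be part of
#'   the interaction.
#' @return One of `"stacked_both"`, `"helix_end"`, `"lonely"`.
#' @export
classify_context <- function(interaction, pos_a, pos_b) {
  if (!interaction_has_pair(interaction, pos_a, pos_b)) {
    stop(sprintf("base pair (%d, %d) is not part of the interaction",
                 pos_a, pos_b), call. = FALSE)
  }
  left <- interaction_has_pair(interaction, pos_a - 1L, pos_b + 1L)
  right <- interaction_has_pair(interaction, pos_a + 1L, pos_b - 1L)
  if (left && right) "stacked_both"
  else if (left || right) "helix_end"
  else "lonely"
}

#' Collect mutable base pairs from predicted interactions
#'
#' Gathers the inter-molecular base pairs considered for compensatory
#' mutation. With `mode = "mfe"` these are exactly the base pairs of the
#' MFE interaction. With `mode = "mfe_subopt"` the set is extended by all
#' base pairs of boundary-unique suboptimal interactions formed within the
#' subsequence windows covered by the MFE interaction, de-duplicated by
#' position pair keeping the best (lowest) source rank. Helix context is
#' classified on the interaction each pair was collected from; for pairs
#' occurring in several interactions the MFE context wins.
#'
#' @inheritParams interaction_energy
#' @param mode `"mfe"` or `"mfe_subopt"`.
#' @param max_subopt Maximum number of suboptimal interactions examined in
#'   `"mfe_subopt"` mode.
#' @return List with `mfe` (the MFE `rri_interaction`, or `NULL` when no
#'   favourable interaction exists) and `pairs`, a data frame with columns
#'   `pos_a`, `pos_b`, `nt_a`, `nt_b`, `context`, `source_rank`.
#' @export
collect_basepairs <- function(seq_a, seq_b, params = energy_parameters(),
                              acc = acc_none(),
                              mode = c("mfe", "mfe_subopt"),
                              max_subopt = 20L) {
  mode <- match.arg(mode)
  seq_a <- as_rna_seq(seq_a, "A"); seq_b <- as_rna_seq(seq_b, "B")
  mfe <- duplex_mfe(seq_a, seq_b, params, acc)
  empty <- data.frame(pos_a = integer(0), pos_b = integer(0),
                      nt_a = character(0), nt_b = character(0),
                      context = character(0), source_rank = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(mfe)) return(list(mfe = NULL, pairs = empty))
  sources <- list(mfe)
  if (mode == "mfe_subopt") {
    region <- list(a = c(mfe$start_a, mfe$end_a),
                   b = c(mfe$start_b, mfe$end_b))
    sources <- enumerate_suboptimals(seq_a, seq_b, params, acc,
                                     max_count = max_subopt,
                                     region = region)
    # defensive: the region-restricted optimum is the MFE itself
    if (length(sources) == 0L) sources <- list(mfe)
  }
  rows <- vector("list", length(sources))
  for (r in seq_along(sources)) {
    it <- sources[[r]]
    p <- it$pairs
    p$context <- vapply(seq_len(nrow(p)), function(k) {
      classify_context(it, p$pos_a[k], p$pos_b[k])
    }, character(1))
    p$source_rank <- r
    rows[[r]] <- p
  }
  all_p <- do.call(rbind, rows)
  # de-duplicate by (pos_a, pos_b), keeping the lowest source rank (the MFE
  # interaction is rank 1, so its context wins for duplicated pairs)
  all_p <- all_p[order(all_p$source_rank), , drop = FALSE]
  all_p <- all_p[!duplicated(all_p[, c("pos_a", "pos_b")]), , drop = FALSE]
  all_p <- all_p[order(all_p$pos_a, all_p$pos_b), , drop = FALSE]
  rownames(all_p) <- NULL
  list(mfe = mfe, pairs = all_p)
}

#' Candidate base-pair filters
#'
#' User-defined constraints applied to collected base pairs before mutation
#' candidates are generated: restriction to specific base-pair types and
#' exclusion of lonely and/or helix-end pairs.
#'
#' Base-pair types in `allowed_bp_types` may be given in either orientation
#' (`"GC"` and `"CG"` as written, or lex-normalized classes); a pair is
#' kept if its ordered type or its lex-sorted class is listed. Defaults
#' keep all six pairable types and exclude lonely pairs (which rarely carry
#' enough stability for a detectable signal) while keeping helix ends.
#'
#' @param allowed_bp_types Character vector of base-pair types.
#' @param exclude_lonely Drop lonely base pairs? (default `TRUE`)
#' @param exclude_helix_ends Drop helix-end base pairs? (default `FALSE`)
#' @return An object of class `candidate_filters`.
#' @export
candidate_filters <- function(allowed_bp_types = PAIRABLE_TYPES,
                              exclude_lonely = TRUE,
                              exclude_helix_ends = FALSE) {
  allowed_bp_types <- toupper(as.character(allowed_bp_types))
  if (length(allowed_bp_types) == 0L) {
    stop("allowed_bp_types must be non-empty", call. = FALSE)
  }
  bad <- setdiff(allowed_bp_types, PAIRABLE_TYPES)
  if (length(bad) > 0L) {
    stop(sprintf("not a pairable base-pair type: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(allowed_bp_types = unique(allowed_bp_types),
                 exclude_lonely = isTRUE(exclude_lonely),
                 exclude_helix_ends = isTRUE(exclude_helix_ends)),
            class = "candidate_filters")
}

# lex-sorted two-letter class of a nucleotide pair ("GC" -> "CG")
lex_bp <- function(nt_a, nt_b) {
  n <- max(length(nt_a), length(nt_b))
  nt_a <- rep_len(nt_a, n); nt_b <- rep_len(nt_b, n)
  vapply(seq_len(n), function(k) {
    paste(sort(c(nt_a[k], nt_b[k])), collapse = "")
  }, character(1))
}

#' Filter collected base pairs
#'
#' Applies [candidate_filters] to a collected base-pair table (see
#' [collect_basepairs]): a pair is kept iff its type is allowed and it is
#' not excluded by its helix context. Input order is preserved; filters
#' compose idempotently.
#'
#' @param bps Data frame with columns `nt_a`, `nt_b`, `context` (plus any
#'   others, carried through).
#' @param filters A [candidate_filters] object.
#' @return The filtered data frame.
#' @export
filter_basepairs <- function(bps, filters = candidate_filters()) {
  stopifnot(inherits(filters, "candidate_filters"))
  if (nrow(bps) == 0L) return(bps)
  allowed_lex <- unique(lex_bp(substr(filters$allowed_bp_types, 1, 1),
                               substr(filters$allowed_bp_types, 2, 2)))
  keep <- lex_bp(bps$nt_a, bps$nt_b) %in% allowed_lex
  if (filters$exclude_lonely) keep <- keep & bps$context != "lonely"
  if (filters$exclude_helix_ends) keep <- keep & bps$context != "helix_end"
  out <- bps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutation alternatives for a wildtype base pair
#'
#' Enumerates the compensatory mutant nucleotide pairs for one wildtype
#' base pair. In `"flip"` mode this is the single nucleotide flip
#' (e.g. GC becomes CG). In `"all"` mode every pairable mutant pair
#' `(x, y)` is returned for which neither mutated nucleotide can still pair
#' with its wildtype counterpart -- `x` must not pair with the wildtype
#' partner on B and `y` must not pair with the wildtype base on A, with GU
#' wobble counting as pairing -- and which differs from the wildtype pair.
#' Every pairable wildtype pair has exactly 3 such alternatives; e.g. for a
#' U-A pair they are GU, GC and AU, while CG is excluded because wildtype U
#' would wobble-pair with mutant G.
#'
#' @param nt_a,nt_b Wildtype nucleotides on sequences A and B (must be
#'   pairable).
#' @param mode `"flip"` or `"all"`.
#' @return Data frame with columns `mut_a`, `mut_b`, one row per mutant
#'   pair, in a fixed deterministic order.
#' @export
mutation_alternatives <- function(nt_a, nt_b, mode = c("flip", "all")) {
  mode <- match.arg(mode)
  if (!is_pairable(nt_a, nt_b)) {
    stop(sprintf("wildtype pair %s%s is not pairable", nt_a, nt_b),
         call. = FALSE)
  }
  if (mode == "flip") {
    return(data.frame(mut_a = nt_b, mut_b = nt_a, stringsAsFactors = FALSE))
  }
  cand <- data.frame(mut_a = substr(PAIRABLE_TYPES, 1, 1),
                     mut_b = substr(PAIRABLE_TYPES, 2, 2),
                     stringsAsFactors = FALSE)
  keep <- !is_pairable(cand$mut_a, rep(nt_b, nrow(cand))) &
    !is_pairable(rep(nt_a, nrow(cand)), cand$mut_b) &
    !(cand$mut_a == nt_a & cand$mut_b == nt_b)
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$mut_a, out$mut_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate compensatory-mutation candidates for a sequence pair
#'
#' Full candidate generation: collect base pairs from the predicted MFE
#' interaction (optionally extended by suboptimals), classify helix
#' context, apply filters, and expand each remaining pair into its mutant
#' alternatives ([mutation_alternatives]). Candidates are identified by
#' `(pos_a, pos_b, mut_a, mut_b)`; duplicates are merged.
#'
#' @inheritParams collect_basepairs
#' @param filters A [candidate_filters] object.
#' @param mutation_mode `"flip"` or `"all"`.
#' @return List with `mfe` and `candidates`, a data frame with columns
#'   `pos_a`, `pos_b`, `nt_a`, `nt_b`, `mut_a`, `mut_b`, `context`,
#'   `source_rank`.
#' @export
generate_candidates <- function(seq_a, seq_b, params = energy_parameters(),
                                acc = acc_none(),
                                mode = c("mfe", "mfe_subopt"),
                                filters = candidate_filters(),
                                mutation_mode = c("flip", "all"),
                                max_subopt = 20L) {
  mode <- match.arg(mode); mutation_mode <- match.arg(mutation_mode)
  coll <- collect_basepairs(seq_a, seq_b, params, acc, mode, max_subopt)
  empty <- data.frame(pos_a = integer(0), pos_b = integer(0),
                      nt_a = character(0), nt_b = character(0),
                      mut_a = character(0), mut_b = character(0),
                      context = character(0), source_rank = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(coll$mfe)) return(list(mfe = NULL, candidates = empty))
  bps <- filter_basepairs(coll$pairs, filters)
  if (nrow(bps) == 0L) return(list(mfe = coll$mfe, candidates = empty))
  rows <- lapply(seq_len(nrow(bps)), function(k) {
    alt <- mutation_alternatives(bps$nt_a[k], bps$nt_b[k], mutation_mode)
    cbind(bps[rep(k, nrow(alt)), c("pos_a", "pos_b", "nt_a", "nt_b"),
              drop = FALSE],
          alt,
          bps[rep(k, nrow(alt)), c("context", "source_rank"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("pos_a", "pos_b", "mut_a", "mut_b")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  list(mfe = coll$mfe, candidates = out)
}
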