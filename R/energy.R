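#' Nearest-neighbor duplex energy parameters
#'
#' Parameter set for the simplified inter-molecular nearest-neighbor model
#' used by the duplex predictor: a 6x6 stacking-increment table over the
#' pairable base-pair types, an affine interior-loop/bulge penalty, a duplex
#' initiation constant, and the maximum unpaired stretch allowed between
#' consecutive base pairs on either sequence.
#'
#' The default stacking increments are Turner-2004-style RNA/RNA free-energy
#' values at 37 degrees C (Watson-Crick stacks after Xia et al. 1998, GU
#' wobble stacks after Mathews et al. 1999), in kcal/mol. The table is
#' stored with rows indexing the 5'-side base pair and columns the 3'-side
#' base pair (both as seen from sequence A), and satisfies the physical
#' strand-exchange symmetry `stack[p, q] == stack[rev(q), rev(p)]`.
#'
#' The loop model is deliberately simple: consecutive base pairs may be
#' separated by up to `max_loop_side` unpaired residues per sequence, at an
#' affine cost `loop_base + loop_per_nt * total_unpaired`. No intra-molecular
#' structure is modelled inside the interaction site.
#'
#' @param stack 6x6 numeric matrix of stacking increments (kcal/mol), with
#'   dimnames over `c("AU","UA","CG","GC","GU","UG")`. Default: embedded
#'   Turner-style table.
#' @param loop_base Affine loop penalty intercept, kcal/mol (default 2.0).
#' @param loop_per_nt Affine loop penalty slope per unpaired nucleotide,
#'   kcal/mol (default 0.4).
#' @param init_penalty Duplex initiation constant, kcal/mol (default 4.09).
#' @param max_loop_side Maximum unpaired stretch between consecutive pairs
#'   on either sequence (default 16).
#' @return An object of class `energy_parameters`.
#' @export
energy_parameters <- function(stack = default_stack_table(),
                              loop_base = 2.0, loop_per_nt = 0.4,
                              init_penalty = 4.09, max_loop_side = 16L) {
  stopifnot(is.matrix(stack), nrow(stack) == 6L, ncol(stack) == 6L,
            !anyNA(stack))
  if (is.null(dimnames(stack))) {
    dimnames(stack) <- list(PAIRABLE_TYPES, PAIRABLE_TYPES)
  }
  stack <- stack[PAIRABLE_TYPES, PAIRABLE_TYPES]
  stopifnot(loop_per_nt >= 0, max_loop_side >= 0)
  structure(list(stack = stack, loop_base = loop_base,
                 loop_per_nt = loop_per_nt, init_penalty = init_penalty,
                 max_loop_side = as.integer(max_loop_side)),
            class = "energy_parameters")
}

#' @export
print.energy_parameters <- function(x, ...) {
  cat("<energy_parameters> nearest-neighbor RNA/RNA duplex model\n")
  cat(sprintf("  init %.2f, loop %.2f + %.2f/nt, max loop side %d\n",
              x$init_penalty, x$loop_base, x$loop_per_nt, x$max_loop_side))
  cat("  stacking increments (kcal/mol):\n")
  print(round(x$stack, 2))
  invisible(x)
}

#' Default RNA/RNA stacking table
#'
#' Builds the embedded Turner-style 6x6 stacking table (see
#' [energy_parameters]) from the 21 unique duplex motifs; the remaining
#' entries follow from strand-exchange symmetry.
#'
#' @return 6x6 numeric matrix (kcal/mol) with pair-type dimnames.
#' @export
default_stack_table <- function() {
  # motif "XY/ZW" means 5'-X Y-3' on A over 3'-Z W-5' on B:
  # 5'-side pair (X,Z), 3'-side pair (Y,W)
  motifs <- c(
    # Watson-Crick / Watson-Crick (Xia et al. 1998)
    "AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33,
    "CU/GA" = -2.08, "CA/GU" = -2.11, "GU/CA" = -2.24,
    "GA/CU" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26, "GC/CG" = -3.42,
    # GU-wobble-containing (Mathews et al. 1999)
    "AG/UU" = -0.55, "AU/UG" = -1.36, "CG/GU" = -1.41, "CU/GG" = -2.11,
    "GG/CU" = -1.53, "GU/CG" = -2.51, "UG/AU" = -1.00, "UU/AG" = -0.76,
    "GG/UU" = -0.50, "GU/UG" = 0.47, "UG/GU" = 0.30
  )
  tab <- matrix(NA_real_, 6, 6,
                dimnames = list(PAIRABLE_TYPES, PAIRABLE_TYPES))
  rev_bp <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (k in seq_along(motifs)) {
    nm <- names(motifs)[k]
    x <- substr(nm, 1, 1); y <- substr(nm, 2, 2)
    z <- substr(nm, 4, 4); w <- substr(nm, 5, 5)
    p1 <- paste0(x, z); p2 <- paste0(y, w)
    tab[p1, p2] <- motifs[[k]]
    tab[rev_bp(p2), rev_bp(p1)] <- motifs[[k]]
  }
  stopifnot(!anyNA(tab))
  tab
}

#' Accessibility providers
#'
#' An accessibility provider supplies the energy penalty `ED(i, j) >= 0`
#' (kcal/mol) needed to make the subsequence window `i..j` (1-based
#' inclusive) of a sequence single-stranded, i.e. to break the
#' intra-molecular base pairs formed by the interacting subsequence. The ED
#' of an empty window is 0.
#'
#' * `acc_none()` returns 0 for every window (fully accessible RNAs).
#' * `acc_constant(per_nt)` charges a constant penalty per covered
#'   nucleotide.
#' * `acc_table(table)` looks windows up in a user-supplied table (columns
#'   `id`, `start`, `end`, `ed`; 1-based inclusive, see
#'   [read_accessibility_table]). A queried window is matched exactly if
#'   listed; otherwise the penalty is pro-rated from the smallest listed
#'   window of the same sequence id that encloses it, and 0 if none does.
#'
#' The zero and constant providers decompose per position, which lets the
#' duplex optimizer fold them into its recursion exactly; the table
#' provider does not (see [duplex_mfe]).
#'
#' @param per_nt Non-negative penalty per nucleotide, kcal/mol.
#' @param table Data frame with columns `id`, `start`, `end`, `ed`.
#' @return An object of class `accessibility_provider`: a list with
#'   elements `ed(seq, start, end)`, `per_nt(seq)` (per-position increments
#'   or `NULL` when not additive) and `label`.
#' @name accessibility
NULL

new_accessibility <- function(ed, per_nt, label) {
  structure(list(ed = ed, per_nt = per_nt, label = label),
            class = "accessibility_provider")
}

#' @rdname accessibility
#' @export
acc_none <- function() {
  new_accessibility(
    ed = function(seq, start, end) {
      if (end < start) 0 else 0
    },
    per_nt = function(seq) numeric(nchar(as_rna_seq(seq)$seq)),
    label = "none"
  )
}

#' @rdname accessibility
#' @export
acc_constant <- function(per_nt) {
  stopifnot(is.numeric(per_nt), length(per_nt) == 1L, per_nt >= 0)
  new_accessibility(
    ed = function(seq, start, end) {
      if (end < start) return(0)
      per_nt * (end - start + 1)
    },
    per_nt = function(seq) rep(per_nt, nchar(as_rna_seq(seq)$seq)),
    label = sprintf("constant %.3f kcal/mol per nt", per_nt)
  )
}

#' @rdname accessibility
#' @export
acc_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("id", "start", "end", "ed") %in% names(table)))
  if (any(table$ed < 0)) stop("ED values must be >= 0", call. = FALSE)
  if (any(table$end < table$start)) {
    stop("accessibility windows must satisfy start <= end", call. = FALSE)
  }
  new_accessibility(
    ed = function(seq, start, end) {
      if (end < start) return(0)
      id <- as_rna_seq(seq)$id
      rows <- table[table$id == id, , drop = FALSE]
      if (nrow(rows) == 0L) return(0)
      exact <- rows$start == start & rows$end == end
      if (any(exact)) return(rows$ed[which(exact)[1L]])
      enclosing <- rows$start <= start & rows$end >= end
      if (!any(enclosing)) return(0)
      rows <- rows[enclosing, , drop = FALSE]
      best <- which.min(rows$end - rows$start)
      rows$ed[best] * (end - start + 1) / (rows$end[best] - rows$start[best] + 1)
    },
    per_nt = NULL,
    label = "window table"
  )
}

#' Read an accessibility table from TSV
#'
#' The file must be tab-separated with a header line and columns `id`
#' (sequence id), `start`, `end` (1-based inclusive window) and `ed`
#' (penalty, kcal/mol, `>= 0`).
#'
#' @param path Path to the TSV file.
#' @return An `accessibility_provider` (see [accessibility]).
#' @export
read_accessibility_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "start", "end", "ed")
  if (!all(need %in% names(tab))) {
    stop(sprintf("accessibility table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  acc_table(tab)
}
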