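# Inter-molecular duplex prediction: MFE interaction, boundary-unique
# suboptimal enumeration, and the exhaustive verification oracle.

# Maximum seq_a x seq_b cell count for exact per-boundary (anchored)
# enumeration; beyond this the caller must restrict the region or use a
# per-position-additive accessibility provider.
ANCHORED_AREA_CAP <- 4096L

encode_seq <- function(seq) {
  match(seq_chars(seq), c("A", "C", "G", "U"))
}

new_interaction <- function(pairs, e_hybrid, ed_a, ed_b) {
  structure(list(
    pairs = pairs,
    e_hybrid = e_hybrid, ed_a = ed_a, ed_b = ed_b,
    e_total = e_hybrid + ed_a + ed_b,
    start_a = min(pairs$pos_a), end_a = max(pairs$pos_a),
    start_b = min(pairs$pos_b), end_b = max(pairs$pos_b)
  ), class = "rri_interaction")
}

#' @export
print.rri_interaction <- function(x, ...) {
  cat(sprintf(
    "<rri_interaction> %d bp, A[%d..%d] x B[%d..%d]\n", nrow(x$pairs),
    x$start_a, x$end_a, x$start_b, x$end_b))
  cat(sprintf("  E = %.2f kcal/mol (hybrid %.2f, ED_A %.2f, ED_B %.2f)\n",
              x$e_total, x$e_hybrid, x$ed_a, x$ed_b))
  invisible(x)
}

# Does the interaction contain the base pair (pos_a, pos_b)?
interaction_has_pair <- function(x, pos_a, pos_b) {
  any(x$pairs$pos_a == pos_a & x$pairs$pos_b == pos_b)
}

pairs_frame <- function(pos_a, pos_b, seq_a, seq_b) {
  ca <- seq_chars(seq_a); cb <- seq_chars(seq_b)
  data.frame(pos_a = as.integer(pos_a), pos_b = as.integer(pos_b),
             nt_a = ca[pos_a], nt_b = cb[pos_b], stringsAsFactors = FALSE)
}

#' Score a fixed set of inter-molecular base pairs
#'
#' Evaluates the model energy of a given antiparallel base-pair set:
#' hybridization energy (initiation + stacking/loop terms) plus the
#' accessibility penalties of the two covered windows. Used for reporting
#' and as an independent check of predicted interactions.
#'
#' @param pos_a,pos_b Equal-length integer vectors of paired positions
#'   (1-based); `pos_a` strictly increasing, `pos_b` strictly decreasing.
#' @param seq_a,seq_b Sequences ([rna_seq] or strings).
#' @param params [energy_parameters].
#' @param acc Accessibility provider (see [accessibility]).
#' @return List with `e_hybrid`, `ed_a`, `ed_b`, `e_total` (kcal/mol).
#' @export
interaction_energy <- function(pos_a, pos_b, seq_a, seq_b,
                               params = energy_parameters(),
                               acc = acc_none()) {
  seq_a <- as_rna_seq(seq_a); seq_b <- as_rna_seq(seq_b)
  stopifnot(length(pos_a) == length(pos_b), length(pos_a) >= 1L)
  if (length(pos_a) > 1L) {
    stopifnot(all(diff(pos_a) > 0), all(diff(pos_b) < 0))
  }
  ca <- seq_chars(seq_a); cb <- seq_chars(seq_b)
  types <- paste0(ca[pos_a], cb[pos_b])
  if (!all(types %in% PAIRABLE_TYPES)) {
    stop("base-pair set contains a non-pairable pair", call. = FALSE)
  }
  e <- params$init_penalty
  if (length(pos_a) > 1L) {
    for (k in 2:length(pos_a)) {
      ga <- pos_a[k] - pos_a[k - 1] - 1L
      gb <- pos_b[k - 1] - pos_b[k] - 1L
      if (ga > params$max_loop_side || gb > params$max_loop_side) {
        stop("unpaired stretch exceeds max_loop_side", call. = FALSE)
      }
      e <- e + if (ga == 0L && gb == 0L) {
        params$stack[types[k - 1], types[k]]
      } else {
        params$loop_base + params$loop_per_nt * (ga + gb)
      }
    }
  }
  ed_a <- acc$ed(seq_a, min(pos_a), max(pos_a))
  ed_b <- acc$ed(seq_b, min(pos_b), max(pos_b))
  list(e_hybrid = e, ed_a = ed_a, ed_b = ed_b, e_total = e + ed_a + ed_b)
}

# Trace one interaction out of the global right-end DP.
trace_global <- function(dp, i, j, seq_a, seq_b, params, acc, eda, edb) {
  pa <- integer(0); pb <- integer(0)
  ci <- i; cj <- j
  while (ci >= 1L) {
    pa <- c(ci, pa); pb <- c(cj, pb)
    ni <- dp$pred_i[ci, cj] + 1L  # C++ 0-based, -1 -> 0 = stop
    nj <- dp$pred_j[ci, cj] + 1L
    ci <- ni; cj <- nj
  }
  pairs <- pairs_frame(pa, pb, seq_a, seq_b)
  ed_a <- sum(eda[min(pa):max(pa)])
  ed_b <- sum(edb[min(pb):max(pb)])
  e_total <- dp$E[i, j]
  new_interaction(pairs, e_hybrid = e_total - ed_a - ed_b,
                  ed_a = ed_a, ed_b = ed_b)
}

#' Minimum-free-energy duplex interaction
#'
#' Computes the most stable inter-molecular interaction that the two RNAs
#' can form under the nearest-neighbor duplex model: the antiparallel
#' base-pair set minimizing total energy (hybridization energy plus the
#' accessibility penalties of the covered windows), subject to the
#' `max_loop_side` constraint. Only favourable interactions
#' (`e_total < 0`) are reported; `NULL` is returned otherwise.
#'
#' For per-position-additive accessibility providers ([acc_none],
#' [acc_constant]) the optimization is exact via a dynamic program over
#' interaction right ends. For window-table providers the optimizer falls
#' back to exact per-boundary enumeration, which requires
#' `nchar(seq_a) * nchar(seq_b) <= 4096`; longer inputs must use an
#' additive provider or be windowed beforehand.
#'
#' Among energy-equal optima the interaction with the lexicographically
#' smallest boundary quadruple `(start_a, end_a, start_b, end_b)` is
#' returned, making the output deterministic.
#'
#' @inheritParams interaction_energy
#' @return An `rri_interaction` (pairs, energies, boundaries) or `NULL`.
#' @examples
#' duplex_mfe("GGGGG", "CCCCC")
#' @export
duplex_mfe <- function(seq_a, seq_b, params = energy_parameters(),
                       acc = acc_none()) {
  seq_a <- as_rna_seq(seq_a, "A"); seq_b <- as_rna_seq(seq_b, "B")
  if (is.null(acc$per_nt)) {
    return(mfe_from_subopt(seq_a, seq_b, params, acc))
  }
  a <- encode_seq(seq_a); b <- encode_seq(seq_b)
  eda <- acc$per_nt(seq_a); edb <- acc$per_nt(seq_b)
  dp <- cpp_duplex_dp(a, b, params$stack, params$loop_base,
                      params$loop_per_nt, params$max_loop_side,
                      params$init_penalty, eda, edb)
  E <- dp$E
  fav <- which(E < -1e-9 & E < dp$inf / 2, arr.ind = TRUE)
  if (nrow(fav) == 0L) return(NULL)
  emin <- min(E[fav])
  tied <- fav[E[fav] <= emin + 1e-9, , drop = FALSE]
  # order tied cells by boundary quadruple (start_a, end_a, start_b, end_b)
  sa <- dp$start_a[tied] + 1L
  eb <- dp$end_b[tied] + 1L
  ord <- order(sa, tied[, 1L], tied[, 2L], eb)[1L]
  trace_global(dp, tied[ord, 1L], tied[ord, 2L], seq_a, seq_b, params, acc,
               eda, edb)
}

mfe_from_subopt <- function(seq_a, seq_b, params, acc) {
  subs <- enumerate_suboptimals(seq_a, seq_b, params, acc, max_count = 1L)
  if (length(subs) == 0L) NULL else subs[[1L]]
}

#' Boundary-unique suboptimal duplex interactions
#'
#' Enumerates favourable interactions (`e_total < 0`) sorted by ascending
#' total energy, reporting at most one interaction -- the best-energy
#' base-pair pattern -- per distinct boundary quadruple
#' `(start_a, end_a, start_b, end_b)`. The head of the list is the MFE
#' interaction (restricted to `region`, if given).
#'
#' The enumeration is exact: every pairable anchor pair starts a forward
#' dynamic program whose cells are exactly the boundary quadruples. Without
#' a `region` this requires `nchar(seq_a) * nchar(seq_b) <= 4096` (the
#' area of the restricted region otherwise); restrict the region, e.g. to
#' the MFE interaction windows, for longer sequences.
#'
#' @inheritParams interaction_energy
#' @param max_count Maximum number of interactions to return (>= 1).
#' @param region Optional list with integer windows `a = c(lo, hi)` and
#'   `b = c(lo, hi)` (1-based inclusive) restricting all base pairs.
#' @return List of `rri_interaction`, possibly empty.
#' @export
enumerate_suboptimals <- function(seq_a, seq_b, params = energy_parameters(),
                                  acc = acc_none(), max_count = 10L,
                                  region = NULL) {
  seq_a <- as_rna_seq(seq_a, "A"); seq_b <- as_rna_seq(seq_b, "B")
  stopifnot(max_count >= 1L)
  n <- nchar(seq_a$seq); m <- nchar(seq_b$seq)
  if (is.null(region)) {
    region <- list(a = c(1L, n), b = c(1L, m))
  }
  stopifnot(is.list(region), length(region$a) == 2L, length(region$b) == 2L)
  ra <- as.integer(region$a); rb <- as.integer(region$b)
  ra[1] <- max(ra[1], 1L); rb[1] <- max(rb[1], 1L)
  ra[2] <- min(ra[2], n); rb[2] <- min(rb[2], m)
  area <- max(0L, ra[2] - ra[1] + 1L) * max(0L, rb[2] - rb[1] + 1L)
  if (area > ANCHORED_AREA_CAP) {
    stop(sprintf(paste0(
      "suboptimal enumeration region area %d exceeds %d; restrict the ",
      "region (e.g. to the MFE windows)"), area, ANCHORED_AREA_CAP),
      call. = FALSE)
  }
  if (area == 0L) return(list())
  a <- encode_seq(seq_a); b <- encode_seq(seq_b)
  cand <- cpp_anchored_enum(a, b, params$stack, params$loop_base,
                            params$loop_per_nt, params$max_loop_side,
                            params$init_penalty,
                            ra[1] - 1L, ra[2] - 1L, rb[1] - 1L, rb[2] - 1L,
                            0)
  if (nrow(cand) == 0L) return(list())
  # 1-based boundaries; add accessibility per boundary window
  cand$start_a <- cand$start_a + 1L; cand$end_a <- cand$end_a + 1L
  cand$start_b <- cand$start_b + 1L; cand$end_b <- cand$end_b + 1L
  cand$ed_a <- vapply(seq_len(nrow(cand)), function(r) {
    acc$ed(seq_a, cand$start_a[r], cand$end_a[r])
  }, numeric(1))
  cand$ed_b <- vapply(seq_len(nrow(cand)), function(r) {
    acc$ed(seq_b, cand$start_b[r], cand$end_b[r])
  }, numeric(1))
  cand$e_total <- cand$e_hybrid + cand$ed_a + cand$ed_b
  cand <- cand[cand$e_total < -1e-9, , drop = FALSE]
  if (nrow(cand) == 0L) return(list())
  ord <- order(cand$e_total, cand$start_a, cand$end_a, cand$start_b,
               cand$end_b)
  cand <- cand[ord, , drop = FALSE]
  cand <- utils::head(cand, max_count)
  lapply(seq_len(nrow(cand)), function(r) {
    tr <- cpp_anchor_trace(a, b, params$stack, params$loop_base,
                           params$loop_per_nt, params$max_loop_side,
                           params$init_penalty,
                           cand$start_a[r] - 1L, cand$end_b[r] - 1L,
                           cand$end_a[r] - 1L, cand$start_b[r] - 1L)
    pairs <- pairs_frame(tr[, 1L] + 1L, tr[, 2L] + 1L, seq_a, seq_b)
    new_interaction(pairs, e_hybrid = cand$e_hybrid[r],
                    ed_a = cand$ed_a[r], ed_b = cand$ed_b[r])
  })
}

#' Exhaustive-enumeration duplex oracle
#'
#' Independent verification oracle for [duplex_mfe]: enumerates every valid
#' antiparallel base-pair set (all chains of pairable position pairs with
#' unpaired stretches within `max_loop_side`), scores each with the model
#' energy, and returns the favourable minimum. Restricted to sequences of
#' at most 12 nt each so the enumeration stays exhaustive and cheap.
#'
#' @inheritParams interaction_energy
#' @return An `rri_interaction` or `NULL`, as for [duplex_mfe].
#' @export
brute_force_duplex_mfe <- function(seq_a, seq_b,
                                   params = energy_parameters(),
                                   acc = acc_none()) {
  enum <- brute_force_enumeration(seq_a, seq_b, params, acc)
  if (nrow(enum$table) == 0L) return(NULL)
  tab <- enum$table[enum$table$e_total < -1e-9, , drop = FALSE]
  if (nrow(tab) == 0L) return(NULL)
  ord <- order(tab$e_total, tab$start_a, tab$end_a, tab$start_b, tab$end_b)
  best <- tab[ord[1L], ]
  chain <- enum$chains[[best$key]]
  seq_a <- as_rna_seq(seq_a, "A"); seq_b <- as_rna_seq(seq_b, "B")
  pairs <- pairs_frame(chain$pos_a, chain$pos_b, seq_a, seq_b)
  new_interaction(pairs, e_hybrid = best$e_hybrid,
                  ed_a = best$ed_a, ed_b = best$ed_b)
}

#' Exhaustive per-boundary enumeration (oracle)
#'
#' Enumerates all valid antiparallel base-pair sets on two short sequences
#' (each at most 12 nt) and keeps, per distinct boundary quadruple, the
#' best-energy set. The independent counterpart of
#' [enumerate_suboptimals].
#'
#' @inheritParams interaction_energy
#' @return Data frame with one row per boundary quadruple: `start_a`,
#'   `end_a`, `start_b`, `end_b`, `e_hybrid`, `ed_a`, `ed_b`, `e_total`,
#'   sorted by ascending `e_total` (all boundaries, including
#'   unfavourable ones).
#' @export
brute_force_boundary_minima <- function(seq_a, seq_b,
                                        params = energy_parameters(),
                                        acc = acc_none()) {
  enum <- brute_force_enumeration(seq_a, seq_b, params, acc)
  tab <- enum$table
  tab <- tab[order(tab$e_total, tab$start_a, tab$end_a, tab$start_b,
                   tab$end_b), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("start_a", "end_a", "start_b", "end_b", "e_hybrid", "ed_a",
          "ed_b", "e_total")]
}

# Depth-first enumeration of all antiparallel chains, tracking the best
# hybridization energy (and one realizing chain) per boundary quadruple.
brute_force_enumeration <- function(seq_a, seq_b, params, acc) {
  seq_a <- as_rna_seq(seq_a, "A"); seq_b <- as_rna_seq(seq_b, "B")
  n <- nchar(seq_a$seq); m <- nchar(seq_b$seq)
  if (n > 12L || m > 12L) {
    stop("brute-force oracle refuses sequences longer than 12 nt",
         call. = FALSE)
  }
  ca <- seq_chars(seq_a); cb <- seq_chars(seq_b)
  W <- params$max_loop_side
  pairable <- outer(ca, cb, FUN = is_pairable)
  best <- new.env(parent = emptyenv())
  chains <- new.env(parent = emptyenv())
  stack_tab <- params$stack
  # current chain as growing vectors (copied only on improvement)
  rec <- function(pa, pb, ehyb, i0, j0) {
    i <- pa[length(pa)]; j <- pb[length(pb)]
    key <- paste(i0, i, j, j0, sep = ",")
    old <- get0(key, envir = best, ifnotfound = Inf)
    if (ehyb < old - 1e-12) {
      assign(key, ehyb, envir = best)
      assign(key, list(pos_a = pa, pos_b = pb), envir = chains)
    }
    if (i < n && j > 1L) {
      for (i2 in (i + 1L):min(n, i + 1L + W)) {
        for (j2 in max(1L, j - 1L - W):(j - 1L)) {
          if (!pairable[i2, j2]) next
          ga <- i2 - i - 1L; gb <- j - j2 - 1L
          step <- if (ga == 0L && gb == 0L) {
            stack_tab[paste0(ca[i], cb[j]), paste0(ca[i2], cb[j2])]
          } else {
            params$loop_base + params$loop_per_nt * (ga + gb)
          }
          rec(c(pa, i2), c(pb, j2), ehyb + step, i0, j0)
        }
      }
    }
    invisible(NULL)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (pairable[i, j]) rec(i, j, params$init_penalty, i, j)
    }
  }
  keys <- ls(best)
  if (length(keys) == 0L) {
    tab <- data.frame(key = character(0), start_a = integer(0),
                      end_a = integer(0), start_b = integer(0),
                      end_b = integer(0), e_hybrid = numeric(0),
                      ed_a = numeric(0), ed_b = numeric(0),
                      e_total = numeric(0), stringsAsFactors = FALSE)
    return(list(table = tab, chains = chains))
  }
  parts <- do.call(rbind, strsplit(keys, ",", fixed = TRUE))
  tab <- data.frame(
    key = keys,
    start_a = as.integer(parts[, 1L]), end_a = as.integer(parts[, 2L]),
    start_b = as.integer(parts[, 3L]), end_b = as.integer(parts[, 4L]),
    e_hybrid = vapply(keys, function(k) get(k, envir = best), numeric(1)),
    stringsAsFactors = FALSE)
  tab$ed_a <- vapply(seq_len(nrow(tab)), function(r) {
    acc$ed(seq_a, tab$start_a[r], tab$end_a[r])
  }, numeric(1))
  tab$ed_b <- vapply(seq_len(nrow(tab)), function(r) {
    acc$ed(seq_b, tab$start_b[r], tab$end_b[r])
  }, numeric(1))
  tab$e_total <- tab$e_hybrid + tab$ed_a + tab$ed_b
  rownames(tab) <- NULL
  list(table = tab, chains = chains)
}
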