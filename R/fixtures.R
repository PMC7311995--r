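# Seeded synthetic sRNA-mRNA-like fixtures: sequence pairs with one
# implanted complementary interaction site and known ground truth.

# run the RNG at a given seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic fixture specification
#'
#' Parameters of the synthetic interacting-pair generator
#' ([generate_interacting_pair]), which emulates an sRNA-mRNA setup: a
#' single complementary interaction site of configurable length and GC
#' content implanted inside random flanking sequence.
#'
#' @param site_length Number of implanted base pairs (>= 1; default 10, a
#'   typical sRNA-mRNA core interaction length).
#' @param gc_fraction Fraction of GC/CG pairs in the implanted site
#'   (default 0.7, GC-rich as in most verified interactions).
#' @param flank_length_a,flank_length_b Flank length in nt added on each
#'   side of the site in sequences A and B (default 15).
#' @param wobble_fraction Fraction of implanted pairs converted to GU
#'   wobble pairs (default 0).
#' @param seed Integer seed; identical specs give identical fixtures.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(site_length = 10L, gc_fraction = 0.7,
                         flank_length_a = 15L, flank_length_b = 15L,
                         wobble_fraction = 0, seed = 1L) {
  stopifnot(site_length >= 1L, gc_fraction >= 0, gc_fraction <= 1,
            flank_length_a >= 0L, flank_length_b >= 0L,
            wobble_fraction >= 0, wobble_fraction <= 1)
  structure(list(site_length = as.integer(site_length),
                 gc_fraction = gc_fraction,
                 flank_length_a = as.integer(flank_length_a),
                 flank_length_b = as.integer(flank_length_b),
                 wobble_fraction = wobble_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

# positions (i, j) starting a pairable diagonal run of length >= k in a
# pairability matrix M (logical)
run_starts <- function(M, k = 3L) {
  n <- nrow(M); m <- ncol(M)
  if (n < k || m < k) {
    return(matrix(FALSE, max(n - k + 1L, 0L), max(m - k + 1L, 0L)))
  }
  R <- M[1:(n - k + 1L), 1:(m - k + 1L), drop = FALSE]
  for (t in seq_len(k - 1L)) {
    R <- R & M[(1L + t):(n - k + 1L + t), (1L + t):(m - k + 1L + t),
               drop = FALSE]
  }
  R
}

# TRUE if the implanted site can pair with itself in a shifted register:
# site_a[i] vs the partner array site_b_rc[j] for i != j, over a run of
# run_len. Runs on the diagonal (i == j) are the implant itself and fine.
site_has_offdiag_run <- function(site_a, site_b_rc, run_len = 3L) {
  if (length(site_a) < run_len) return(FALSE)
  R <- run_starts(outer(site_a, site_b_rc, is_pairable), run_len)
  diag(R) <- FALSE
  any(R)
}

# The implant should stay the dominant site under its intended flip
# mutations. Requiring flip variants to be free of 3-runs like the
# wildtype is statistically unsatisfiable (every flip creates some short
# complementarity), so variants are held to a longer-run bound: a shifted
# run must stay below max(4, L - 4) pairs, short enough that its helix
# cannot rival the implant with one pair broken.
site_variant_run_len <- function(L) max(4L, L - 4L)

site_or_flips_have_offdiag_run <- function(site_a, site_b_rc) {
  if (site_has_offdiag_run(site_a, site_b_rc, 3L)) return(TRUE)
  L <- length(site_a)
  if (L < 3L) return(FALSE)
  vlen <- site_variant_run_len(L)
  for (k in seq_len(L)[-c(1L, L)]) {
    va <- site_a; vb <- site_b_rc
    va[k] <- site_b_rc[k]  # flip: A takes the B partner letter
    vb[k] <- site_a[k]
    if (site_has_offdiag_run(va, site_b_rc, vlen) ||
        site_has_offdiag_run(site_a, vb, vlen) ||
        site_has_offdiag_run(va, vb, vlen)) {
      return(TRUE)
    }
  }
  FALSE
}

# Constructively sample a flank of length len that cannot form an
# antiparallel pairable run of 3+ with any of the site variants in
# u_list (each already reversed so runs are matrix diagonals): letters
# are placed 5'->3' by randomized depth-first search with backtracking,
# trying the four nucleotides in random order at each position and
# rejecting letters that complete a run. Capped at 200000 search nodes.
draw_clean_flank <- function(len, u_list) {
  if (len == 0L) return(character(0))
  nts <- c("A", "C", "G", "U")
  fl <- character(len)
  options <- vector("list", len)
  nodes <- 0L
  i <- 1L
  options[[1L]] <- sample(nts)
  while (i >= 1L) {
    if (length(options[[i]]) == 0L) {
      i <- i - 1L  # dead end: backtrack
      next
    }
    x <- options[[i]][1L]
    options[[i]] <- options[[i]][-1L]
    nodes <- nodes + 1L
    if (nodes > 200000L) {
      stop("flank sampling exceeded the search budget", call. = FALSE)
    }
    if (!flank_letter_completes_run(fl, i, x, u_list)) {
      fl[i] <- x
      if (i == len) return(fl)
      i <- i + 1L
      options[[i]] <- sample(nts)
    }
  }
  stop("no flank satisfies the pairing constraints", call. = FALSE)
}

# 4x4 logical pairability lookup over integer-encoded nucleotides
# (A=1, C=2, G=3, U=4): AU, UA, CG, GC, GU, UG
PAIRABLE_INT <- matrix(c(
  # A      C      G      U      (second nucleotide)
  FALSE, FALSE, FALSE, TRUE,   # A
  FALSE, FALSE, TRUE,  FALSE,  # C
  FALSE, TRUE,  FALSE, TRUE,   # G
  TRUE,  FALSE, TRUE,  FALSE   # U
), nrow = 4, byrow = TRUE)

# TRUE if the assembled pair (integer-encoded) contains an antiparallel
# pairable run of >= run_len whose register differs from the implant
# register (reg_sum = pos_a + pos_b along the implanted diagonal)
assembly_has_offreg_run <- function(a_int, b_int, reg_sum, run_len) {
  nb <- length(b_int)
  M <- PAIRABLE_INT[a_int, rev(b_int), drop = FALSE]
  R <- run_starts(M, run_len)
  if (!any(R)) return(FALSE)
  idx <- which(R, arr.ind = TRUE)
  # column j' indexes reversed B: original register sum = i + nb - j' + 1
  any(idx[, 1L] + nb - idx[, 2L] + 1L != reg_sum)
}

flank_letter_completes_run <- function(fl, i, x, u_list) {
  if (i < 3L) return(FALSE)
  for (u in u_list) {
    m <- length(u)
    if (m < 3L) next
    for (j in 3:m) {
      if (is_pairable(x, u[j]) &&
          is_pairable(fl[i - 1L], u[j - 1L]) &&
          is_pairable(fl[i - 2L], u[j - 2L])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Generate a synthetic interacting sequence pair
#'
#' Builds a seeded sequence pair with one implanted interaction site:
#' sequence A carries a random site (GC content per `gc_fraction`), and
#' sequence B carries its reverse complement, with a `wobble_fraction` of
#' the implanted pairs converted to GU wobble pairs.
#'
#' Seeded rejection/constructive sampling keeps the implant the dominant
#' site, in the wildtype and under the single-base-pair flips that
#' candidate evaluation applies: the site is redrawn (at most 10000 times)
#' while its shifted self-alignment has a pairable run of 3+ pairs in the
#' wildtype, or of `max(4, site_length - 4)`+ pairs in any variant with
#' one interior pair flipped (flip variants always admit some short
#' complementarity, so they are held to this longer-run bound, below which
#' a competing helix cannot rival the broken implant); each flank is built
#' letter-by-letter so that it can never form a 3+ run with the other
#' sequence's site or any of its flip variants (at most 2000 restarts).
#' Identical specs (including the seed) give identical output.
#'
#' @param spec A [fixture_spec].
#' @return List with `seq_a`, `seq_b` ([rna_seq]), `site_a`, `site_b`
#'   (integer `c(start, end)` windows, 1-based inclusive) and `pairs`
#'   (data frame `pos_a`, `pos_b`, `nt_a`, `nt_b` of the implanted pairs,
#'   `pos_a` ascending).
#' @export
generate_interacting_pair <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    L <- spec$site_length
    n_gc <- round(spec$gc_fraction * L)
    for (try in seq_len(10000L)) {
      gc_pos <- if (n_gc > 0L) sample(L, n_gc) else integer(0)
      site_a <- character(L)
      site_a[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
      site_a[setdiff(seq_len(L), gc_pos)] <-
        sample(c("A", "U"), L - n_gc, replace = TRUE)
      site_b_rc <- unname(COMPLEMENT[site_a])  # partner of site_a[k]
      n_wob <- round(spec$wobble_fraction * L)
      if (n_wob > 0L) {
        wob_pos <- sample(L, n_wob)
        for (k in wob_pos) {
          # convert pair to wobble where possible: GC -> GU, AU -> GU on B
          if (site_a[k] == "G") site_b_rc[k] <- "U"
          else if (site_a[k] == "U") site_b_rc[k] <- "G"
          else if (site_a[k] == "A") { site_a[k] <- "G"; site_b_rc[k] <- "U" }
          else if (site_a[k] == "C") { site_a[k] <- "U"; site_b_rc[k] <- "G" }
        }
      }
      # the implant must be the only site, in the wildtype and under any
      # single interior flip: reject site sequences whose *shifted*
      # self-alignment (off the implanted diagonal) can form a pairable
      # run of 3+ (longer bound for flip variants, see Details), which
      # would constitute a competing second site
      if (site_or_flips_have_offdiag_run(site_a, site_b_rc)) {
        if (try == 10000L) {
          stop("site rejection sampling exceeded 10000 attempts",
               call. = FALSE)
        }
        next
      }
      # flanks must not pair the other sequence's site, wildtype or any
      # single interior flip of it (candidate evaluation mutates the
      # site); reversed site variants so that runs lie on matrix
      # diagonals. An unsatisfiable site (possible with wobble-heavy
      # implants) is redrawn.
      u_for_a <- c(list(site_b_rc),
                   lapply(seq_len(L)[-c(1L, L)], function(k) {
                     vb <- site_b_rc; vb[k] <- site_a[k]; vb
                   }))
      u_for_b <- c(list(rev(site_a)),
                   lapply(seq_len(L)[-c(1L, L)], function(k) {
                     va <- site_a; va[k] <- site_b_rc[k]; rev(va)
                   }))
      flanks <- tryCatch(list(
        fa5 = draw_clean_flank(spec$flank_length_a, u_for_a),
        fa3 = draw_clean_flank(spec$flank_length_a, u_for_a),
        fb5 = draw_clean_flank(spec$flank_length_b, u_for_b),
        fb3 = draw_clean_flank(spec$flank_length_b, u_for_b)),
        error = function(e) NULL)
      if (!is.null(flanks)) {
        # final whole-assembly guard: under any interior flip, no
        # off-register pairable run as long as the implant may remain
        # (shorter runs have strictly fewer stacks than the implant
        # helix, so they cannot out-stabilize it); sub-runs allowed by
        # the piecewise checks above can otherwise concatenate across
        # the flank/site borders into a competing helix
        nts <- c("A", "C", "G", "U")
        a_int <- match(c(flanks$fa5, site_a, flanks$fa3), nts)
        b_int <- match(c(flanks$fb5, rev(site_b_rc), flanks$fb3), nts)
        reg_sum <- spec$flank_length_a + spec$flank_length_b + L + 1L
        run_len <- max(4L, L)
        clean <- TRUE
        for (k in seq_len(L)[-c(1L, L)]) {
          pa <- spec$flank_length_a + k
          pb <- spec$flank_length_b + L - k + 1L
          am <- a_int; am[pa] <- match(site_b_rc[k], nts)
          bm <- b_int; bm[pb] <- match(site_a[k], nts)
          if (assembly_has_offreg_run(am, b_int, reg_sum, run_len) ||
              assembly_has_offreg_run(a_int, bm, reg_sum, run_len) ||
              assembly_has_offreg_run(am, bm, reg_sum, run_len)) {
            clean <- FALSE
            break
          }
        }
        if (clean) break
      }
      if (try == 10000L) {
        stop("site rejection sampling exceeded 10000 attempts",
             call. = FALSE)
      }
    }
    # sequence B carries the partners antiparallel: reverse order
    site_b <- rev(site_b_rc)
    fa5 <- flanks$fa5; fa3 <- flanks$fa3
    fb5 <- flanks$fb5; fb3 <- flanks$fb3
    sa <- c(fa5, site_a, fa3)
    sb <- c(fb5, site_b, fb3)
    a_start <- spec$flank_length_a + 1L
    b_start <- spec$flank_length_b + 1L
    pos_a <- a_start:(a_start + L - 1L)
    # site_a[k] pairs with site_b_rc[k], which sits at B index (L - k + 1)
    # within the site window
    pos_b <- b_start + L - seq_len(L)
    seq_a <- rna_seq(paste(sa, collapse = ""), id = "synthA")
    seq_b <- rna_seq(paste(sb, collapse = ""), id = "synthB")
    pairs <- data.frame(pos_a = pos_a, pos_b = pos_b,
                        nt_a = site_a, nt_b = site_b_rc,
                        stringsAsFactors = FALSE)
    list(seq_a = seq_a, seq_b = seq_b,
         site_a = c(a_start, a_start + L - 1L),
         site_b = c(b_start, b_start + L - 1L),
         pairs = pairs)
  })
}

#' Generate a synthetic known-CoM benchmark table
#'
#' Produces `n_pairs` seeded synthetic records in the benchmark input
#' schema (see [read_known_coms]): each record is an interacting pair from
#' [generate_interacting_pair] whose known compensatory mutation is the
#' nucleotide flip of a randomly chosen interior GC pair of the implanted
#' site (interior = stacked on both sides within the implant). Records
#' whose site lacks an interior GC pair are regenerated with a derived
#' seed, up to 100 attempts each.
#'
#' @param n_pairs Number of records (>= 1).
#' @param spec Template [fixture_spec]; each record r uses seed
#'   `spec$seed + r` (redraws add multiples of 1000).
#' @param path Optional CSV destination; when given the table is written
#'   there.
#' @return Data frame with columns `pair_id`, `seq_a`, `seq_b`, `pos_a`,
#'   `pos_b`, `wt_bp`, `mut_bp` (and the fixture list as attribute
#'   `"fixtures"`).
#' @export
generate_known_com_table <- function(n_pairs, spec = fixture_spec(),
                                     path = NULL) {
  stopifnot(n_pairs >= 1L)
  recs <- vector("list", n_pairs)
  fixtures <- vector("list", n_pairs)
  for (r in seq_len(n_pairs)) {
    rec <- NULL
    for (try in 0:99) {
      sp <- spec
      sp$seed <- spec$seed + r + 1000L * try
      fx <- generate_interacting_pair(sp)
      p <- fx$pairs
      L <- nrow(p)
      interior <- which(seq_len(L) > 1L & seq_len(L) < L &
                          lex_bp(p$nt_a, p$nt_b) == "CG")
      if (length(interior) == 0L) next
      k <- with_seed(sp$seed + 500L, {
        interior[sample.int(length(interior), 1L)]
      })
      rec <- data.frame(
        pair_id = sprintf("synth%03d", r),
        seq_a = fx$seq_a$seq, seq_b = fx$seq_b$seq,
        pos_a = p$pos_a[k], pos_b = p$pos_b[k],
        wt_bp = paste0(p$nt_a[k], p$nt_b[k]),
        mut_bp = paste0(p$nt_b[k], p$nt_a[k]),
        stringsAsFactors = FALSE)
      fixtures[[r]] <- fx
      break
    }
    if (is.null(rec)) {
      stop(sprintf("record %d: no interior GC pair after 100 redraws", r),
           call. = FALSE)
    }
    recs[[r]] <- rec
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "fixtures") <- fixtures
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  }
  out
}
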