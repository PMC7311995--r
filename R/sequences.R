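#' RNA sequence objects
#'
#' An `rna_seq` is a validated single RNA sequence: an id label plus a
#' residue string over `A`, `C`, `G`, `U` in 5'-to-3' orientation. Input is
#' case-folded to upper case and DNA-style `T` is normalized to `U`; any
#' other character is rejected with its position reported.
#'
#' @param residues Character scalar, the residue string (ACGU/T, any case).
#' @param id Character scalar label (default `"seq"`).
#' @return An object of class `rna_seq`: a list with elements `id` and
#'   `seq` (the normalized residue string).
#' @examples
#' rna_seq("acgt", id = "x")
#' @export
rna_seq <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  s <- toupper(residues)
  s <- gsub("T", "U", s, fixed = TRUE)
  if (nchar(s) == 0L) stop("RNA sequence must be non-empty", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop(sprintf("illegal residue '%s' at position %d in sequence '%s'",
                 chars[bad[1L]], bad[1L], id), call. = FALSE)
  }
  structure(list(id = as.character(id), seq = s), class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("<rna_seq> %s (%d nt)\n%s\n", x$id, nchar(x$seq), x$seq))
  invisible(x)
}

#' @export
as.character.rna_seq <- function(x, ...) x$seq

# Coerce a user-supplied sequence argument (rna_seq or plain string) into a
# validated rna_seq.
as_rna_seq <- function(x, id = "seq") {
  if (inherits(x, "rna_seq")) return(x)
  rna_seq(x, id = id)
}

# Residues as a character vector, for positional work.
seq_chars <- function(x) strsplit(as_rna_seq(x)$seq, "", fixed = TRUE)[[1L]]

#' Canonical and wobble base-pairing test
#'
#' A nucleotide pair is pairable if it is a Watson-Crick pair (`AU`, `UA`,
#' `GC`, `CG`) or a GU wobble pair (`GU`, `UG`). Wobble pairs are counted as
#' pairable both for duplex formation and for the wildtype/mutant
#' incompatibility checks of compensatory-mutation design.
#'
#' @param nt_a,nt_b Character vectors of residues in `A`, `C`, `G`, `U`
#'   (recycled to common length).
#' @return Logical vector.
#' @examples
#' is_pairable("G", "U")  # TRUE (wobble)
#' is_pairable("A", "G")  # FALSE
#' @export
is_pairable <- function(nt_a, nt_b) {
  n <- max(length(nt_a), length(nt_b))
  nt_a <- rep_len(as.character(nt_a), n)
  nt_b <- rep_len(as.character(nt_b), n)
  ok <- c("A", "C", "G", "U")
  if (any(!nt_a %in% ok) || any(!nt_b %in% ok)) {
    stop("residues must be one of A, C, G, U", call. = FALSE)
  }
  paste0(nt_a, nt_b) %in% PAIRABLE_TYPES
}

# The six pairable ordered nucleotide pairs (first letter = sequence A).
PAIRABLE_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Apply a point mutation to a sequence
#'
#' Returns a copy of the sequence with the residue at `pos` (1-based)
#' replaced by `nt`; the input object is unchanged.
#'
#' @param seq An [rna_seq] or plain residue string.
#' @param pos 1-based position to mutate.
#' @param nt Replacement residue (one of `A`, `C`, `G`, `U`).
#' @return An `rna_seq`.
#' @export
apply_mutation <- function(seq, pos, nt) {
  seq <- as_rna_seq(seq)
  n <- nchar(seq$seq)
  if (!is.numeric(pos) || length(pos) != 1L || pos < 1L || pos > n) {
    stop(sprintf("mutation position %s out of range 1..%d", format(pos), n),
         call. = FALSE)
  }
  nt <- as.character(nt)
  if (!nt %in% c("A", "C", "G", "U")) {
    stop("mutant residue must be one of A, C, G, U", call. = FALSE)
  }
  chars <- seq_chars(seq)
  chars[as.integer(pos)] <- nt
  rna_seq(paste(chars, collapse = ""), id = seq$id)
}

#' Read RNA sequences from a FASTA file
#'
#' Parses a (multi-record) FASTA file into a list of [rna_seq] objects.
#' Residues are upper-cased and `T` is normalized to `U`; sequence ids are
#' taken from the header up to the first whitespace. Illegal residues are
#' rejected with their position.
#'
#' @param path Path to a FASTA file.
#' @return List of `rna_seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path),
                               call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path),
                              call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    out[[k]] <- rna_seq(as.character(set[[k]]), id = ids[k])
  }
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs A list of [rna_seq] (or residue strings).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_seq")) seqs <- list(seqs)
  seqs <- lapply(seqs, as_rna_seq)
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$seq)))
  writeLines(lines, path)
  invisible(path)
}
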