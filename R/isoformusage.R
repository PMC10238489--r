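# Splice-isoform usage from exon-junction read counts, and coding
# substitution classification.
#
# An isoform model maps each isoform to its ordered exon list; junctions are
# consecutive exon pairs. Relative isoform frequencies are recovered from
# junction-spanning read counts by non-negative least squares with a free
# global scale, then normalised to sum to 1.

#' Build an isoform model
#'
#' @param isoforms named list: isoform id -> ordered character/integer vector
#'   of exon identifiers (>= 2 exons each; shared exons share identifiers).
#' @return object of class `isoform_model`.
#' @export
isoform_model <- function(isoforms) {
  stopifnot(is.list(isoforms), length(isoforms) >= 1,
            !is.null(names(isoforms)), all(nzchar(names(isoforms))))
  isoforms <- lapply(isoforms, as.character)
  if (any(vapply(isoforms, length, integer(1)) < 2))
    stop("every isoform needs at least 2 exons")
  if (anyDuplicated(names(isoforms))) stop("duplicated isoform ids")
  structure(list(isoforms = isoforms), class = "isoform_model")
}

#' Junction membership matrix
#'
#' One row per distinct exon junction, one column per isoform; entry 1 iff
#' the junction's exon pair is consecutive in that isoform. Row names are
#' "donor-acceptor".
#'
#' @param model an [isoform_model()].
#' @export
junction_matrix <- function(model) {
  stopifnot(inherits(model, "isoform_model"))
  juncs <- lapply(model$isoforms, function(ex)
    paste(ex[-length(ex)], ex[-1], sep = "-"))
  all_j <- unique(unlist(juncs))
  if (anyDuplicated(all_j)) stop("duplicate junction rows")
  M <- vapply(juncs, function(j) as.integer(all_j %in% j),
              integer(length(all_j)))
  M <- matrix(M, nrow = length(all_j),
              dimnames = list(all_j, names(model$isoforms)))
  M
}

# Lawson-Hanson active-set non-negative least squares: min ||A x - b||,
# x >= 0. Hand-rolled (no NNLS package in the environment); exact for the
# small junction systems used here.
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Estimate relative isoform frequencies from junction counts
#'
#' Solves counts ~ scale x (M f) by Poisson-weighted non-negative least
#' squares over the scaled frequencies (rows weighted by 1/sqrt(count + 1),
#' the first-order variance-stabilising weight for count data), then
#' normalises to sum 1. Junctions observed in the
#' counts but absent from the model are reported separately, never dropped
#' silently; isoforms with identical junction signatures (rank-deficient
#' columns) are flagged non-identifiable.
#'
#' @param counts named numeric vector of junction read counts (names
#'   "donor-acceptor"), or a data.frame with columns `donor_exon`,
#'   `acceptor_exon`, `count` as read by [read_junction_counts()].
#' @param model an [isoform_model()].
#' @return object of class `isoform_frequencies`: `frequencies` (named,
#'   sums to 1), `residual` (norm of the least-squares residual),
#'   `novel_junctions` (counts on junctions outside the model),
#'   `non_identifiable` (list of isoform id groups with identical columns).
#' @export
estimate_isoform_frequencies <- function(counts, model) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("donor_exon", "acceptor_exon", "count") %in% names(counts)))
    counts <- stats::setNames(counts$count,
                              paste(counts$donor_exon, counts$acceptor_exon,
                                    sep = "-"))
  }
  if (is.null(names(counts))) stop("counts must be named 'donor-acceptor'")
  if (any(counts < 0)) stop("counts must be non-negative")
  M <- junction_matrix(model)
  novel <- counts[!names(counts) %in% rownames(M)]
  counts <- counts[names(counts) %in% rownames(M)]
  if (!length(counts) || all(counts == 0))
    stop("no nonzero counts on model junctions")
  b <- stats::setNames(numeric(nrow(M)), rownames(M))
  b[names(counts)] <- counts
  groups <- split(colnames(M), apply(M, 2, paste, collapse = ""))
  non_ident <- unname(Filter(function(g) length(g) > 1, groups))
  # Poisson weighting: junction counts have variance ~ their mean, so rows
  # are scaled by 1 / sqrt(count + 1) before the non-negative fit
  wts <- 1 / sqrt(b + 1)
  g <- nnls_fit(M * wts, b * wts)
  if (sum(g) <= 0) stop("estimation degenerate: all frequencies zero")
  f <- stats::setNames(g / sum(g), colnames(M))
  structure(list(frequencies = f,
                 residual = sqrt(sum((b - M %*% g)^2)),
                 novel_junctions = novel,
                 non_identifiable = non_ident),
            class = "isoform_frequencies")
}

#' Ratio of two isoform frequencies
#'
#' @param freqs an `isoform_frequencies` result (or named numeric vector).
#' @param a,b isoform ids; `b` must have nonzero frequency.
#' @export
isoform_ratio <- function(freqs, a, b) {
  f <- if (inherits(freqs, "isoform_frequencies")) freqs$frequencies else freqs
  if (!all(c(a, b) %in% names(f))) stop("unknown isoform id")
  if (f[[b]] <= 0) stop("denominator isoform has zero frequency")
  unname(f[[a]] / f[[b]])
}

#' Simulate junction-spanning read counts
#'
#' Multinomial reads over the model's junctions with probabilities
#' proportional to M f: the generative model the estimator inverts.
#'
#' @param model an [isoform_model()].
#' @param freqs named isoform frequencies (summing to 1).
#' @param n_reads total junction-spanning reads.
#' @param seed optional integer seed.
#' @return named count vector over the model's junctions.
#' @export
simulate_junction_reads <- function(model, freqs, n_reads, seed = NULL) {
  M <- junction_matrix(model)
  stopifnot(setequal(names(freqs), colnames(M)))
  p <- as.numeric(M %*% freqs[colnames(M)])
  p <- p / sum(p)
  cts <- with_seed(seed, as.numeric(stats::rmultinom(1, n_reads, p)))
  stats::setNames(cts, rownames(M))
}

#' Classify a single-base codon substitution
#'
#' Translates the reference codon and the codon with `alt_base` substituted
#' at `position` (1 = first codon position) under the standard genetic code
#' and classifies the change as synonymous, missense, or nonsense (an
#' amino-acid codon turned into a stop, e.g. CAG -> TAG, Gln -> stop).
#'
#' @param ref_codon 3-letter reference codon over A/C/G/T.
#' @param position position within the codon, 1..3.
#' @param alt_base substituted base, different from the reference base.
#' @return list: `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa` (one-letter,
#'   "*" = stop), `class`.
#' @export
classify_codon_substitution <- function(ref_codon, position, alt_base) {
  ref_codon <- toupper(ref_codon); alt_base <- toupper(alt_base)
  if (!grepl("^[ACGT]{3}$", ref_codon)) stop("invalid reference codon")
  if (!alt_base %in% c("A", "C", "G", "T")) stop("invalid substituted base")
  position <- as.integer(position)
  if (position < 1 || position > 3) stop("position must be 1, 2 or 3")
  if (substr(ref_codon, position, position) == alt_base)
    stop("alt base equals the reference base at that position")
  alt_codon <- ref_codon
  substr(alt_codon, position, position) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon]); alt_aa <- unname(code[alt_codon])
  cls <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*" && ref_aa != "*") "nonsense"
  else "missense"
  list(ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, class = cls)
}

#' Read a junction-count table (TSV)
#'
#' Columns: donor_exon, acceptor_exon, count.
#' @param path TSV file.
#' @export
read_junction_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("donor_exon", "acceptor_exon", "count") %in% names(d)))
  if (any(d$count < 0)) stop("counts must be non-negative")
  d
}

#' Read an isoform model from JSON
#'
#' JSON object: isoform id -> array of exon identifiers.
#' @param path JSON file.
#' @export
read_isoform_model <- function(path) {
  isoform_model(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' A synthetic six-isoform model of an alternatively spliced RhoGEF locus
#'
#' Stand-in for a 15-exon locus expressing six splice isoforms where exon 8
#' is a cassette exon carried by two of the six (the pair silenced by a
#' nonsense substitution in that exon). Exon structures are synthetic: they
#' reproduce the structural features relevant to junction analysis (a
#' cassette exon, pairwise-distinct junction signatures) rather than any
#' database annotation. Default frequencies put ~91% of transcripts on the
#' two major isoforms RA and RB.
#'
#' @return list: `model` (an [isoform_model()]) and `frequencies` (named,
#'   summing to 1).
#' @export
six_isoform_model <- function() {
  e <- function(...) as.character(c(...))
  model <- isoform_model(list(
    RA = e(1:7, 9:15),            # skips cassette exon 8
    RB = e(1:15),                 # full-length, carries exon 8
    RC = e(1:7, 9:11, 13:15),     # skips 8 and 12
    RD = e(1:11, 13:15),          # carries 8, skips 12
    RE = e(2:7, 9:15),            # alternative start, skips 8
    RF = e(1:4, 6:7, 9:15)))      # skips 5 and 8
  freqs <- c(RA = 0.455, RB = 0.455, RC = 0.0225, RD = 0.0225,
             RE = 0.0225, RF = 0.0225)
  list(model = model, frequencies = freqs)
}
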