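#' Haplotype alignment with deme assignments
#'
#' The container all summary statistics operate on: a samples-by-sites matrix
#' of discrete states (0/1 for simulated infinite-sites data, or nucleotide
#' characters for read-in alignments), the positions those columns occupy in
#' the full sequence, the total sequence length `L`, and a deme label per
#' sample. Monomorphic columns need not be stored; per-site quantities such
#' as nucleotide diversity always divide by `L`.
#'
#' @param genotypes Matrix (samples x sites) of single-character states or
#'   integers; zero columns are allowed.
#' @param deme Character vector of deme labels, one per row.
#' @param seq_length Total sequence length `L` (>= ncol(genotypes)).
#' @param positions Optional integer positions (1..L) of the stored columns.
#' @param sample_ids Sample identifiers; defaults to rownames or `s1..sn`.
#' @return Object of class `haplotype_alignment`: list with `genotypes`,
#'   `positions`, `seq_length`, `samples` (tibble `sample_id`, `deme_id`).
#' @examples
#' geno <- rbind(A = c("A", "A", "A"), B = c("A", "A", "T"),
#'               C = c("T", "T", "A"), D = c("T", "T", "T"))
#' aln <- haplotype_alignment(geno, deme = c("p1", "p1", "p2", "p2"),
#'                            seq_length = 3)
#' segregating_sites(aln)
#' @export
haplotype_alignment <- function(genotypes, deme, seq_length,
                                positions = NULL, sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  s <- ncol(genotypes)
  if (length(deme) != n)
    stop("deme must have one label per sample row", call. = FALSE)
  if (seq_length < s)
    stop("seq_length (", seq_length, ") is smaller than the number of stored ",
         "sites (", s, ")", call. = FALSE)
  if (is.null(positions)) positions <- seq_len(s)
  if (length(positions) != s)
    stop("positions must have one entry per site column", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(genotypes)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  }
  rownames(genotypes) <- sample_ids
  structure(list(genotypes = genotypes,
                 positions = as.integer(positions),
                 seq_length = seq_length,
                 samples = tibble::tibble(sample_id = sample_ids,
                                          deme_id = as.character(deme))),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("<haplotype_alignment> ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " stored sites (L = ", x$seq_length, "), ",
      length(unique(x$samples$deme_id)), " demes\n", sep = "")
  invisible(x)
}

subset_rows <- function(aln, deme) {
  if (is.null(deme)) return(seq_len(nrow(aln$genotypes)))
  rows <- which(aln$samples$deme_id %in% deme)
  if (!length(rows))
    stop("no samples in deme(s): ", paste(deme, collapse = ", "),
         call. = FALSE)
  rows
}

#' Number of segregating sites
#'
#' Counts the positions that are polymorphic (more than one state present)
#' within a deme or across the full sample set.
#'
#' @param aln A [haplotype_alignment()].
#' @param deme Deme label(s) to restrict to, or `NULL` for all samples.
#'   A single-sample subset carries no polymorphism and yields 0.
#' @return Integer count.
#' @export
segregating_sites <- function(aln, deme = NULL) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  rows <- subset_rows(aln, deme)
  m <- aln$genotypes[rows, , drop = FALSE]
  if (ncol(m) == 0 || nrow(m) < 2) return(0L)
  ref <- matrix(m[1L, ], nrow(m), ncol(m), byrow = TRUE)
  sum(colSums(m != ref) > 0)
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences over all unordered sample pairs in
#' the subset, divided by the sequence length `L` (per-site pi). A deme with
#' a single sample has no pairs and is reported as 0 (the fixed-length
#' summary vector requires a defined value).
#'
#' @inheritParams segregating_sites
#' @return Per-site nucleotide diversity in `[0, 1]`.
#' @export
nucleotide_diversity <- function(aln, deme = NULL) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  rows <- subset_rows(aln, deme)
  m <- aln$genotypes[rows, , drop = FALSE]
  n <- nrow(m)
  if (n < 2 || ncol(m) == 0) return(0)
  sum(within_diff_pairs(m)) / choose(n, 2) / aln$seq_length
}

# per-site count of differing unordered pairs: (n^2 - sum_s c_s^2) / 2
within_diff_pairs <- function(m) {
  n <- nrow(m)
  states <- unique(as.vector(m))
  ss <- 0
  for (s in states) ss <- ss + colSums(m == s)^2
  (n^2 - ss) / 2
}

#' Pairwise Fst (Hudson estimator)
#'
#' `Fst = 1 - Hw / Hb` on haplotype data, with `Hw` the unweighted mean of
#' the two within-deme per-site diversities and `Hb` the mean per-site
#' difference over all between-deme sample pairs. When `Hb = 0` (no
#' between-deme diversity) the estimator is undefined and 0 is returned by
#' convention. Negative estimates are reported as computed unless
#' `clamp_negative = TRUE`.
#'
#' @inheritParams segregating_sites
#' @param deme_a,deme_b The two deme labels.
#' @param clamp_negative Truncate negative estimates to 0.
#' @return Fst estimate (<= 1).
#' @export
pairwise_fst <- function(aln, deme_a, deme_b, clamp_negative = FALSE) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  ra <- subset_rows(aln, deme_a)
  rb <- subset_rows(aln, deme_b)
  ma <- aln$genotypes[ra, , drop = FALSE]
  mb <- aln$genotypes[rb, , drop = FALSE]
  na <- nrow(ma); nb <- nrow(mb)
  L <- aln$seq_length
  pia <- nucleotide_diversity(aln, deme_a)
  pib <- nucleotide_diversity(aln, deme_b)
  if (ncol(ma) == 0) return(0)
  states <- unique(as.vector(aln$genotypes[c(ra, rb), , drop = FALSE]))
  cross <- 0
  for (s in states) cross <- cross + colSums(ma == s) * colSums(mb == s)
  hb <- sum(na * nb - cross) / (na * nb) / L
  if (hb == 0) return(0)
  fst <- 1 - mean(c(pia, pib)) / hb
  if (clamp_negative) max(fst, 0) else fst
}

#' Names and order of the canonical summary vector
#'
#' For `d` demes in configuration order the canonical composition has
#' `2 d + 5 + d (d - 1) / 2` entries: per-deme segregating sites, their mean,
#' SD and the total; per-deme nucleotide diversity with mean and SD; and
#' pairwise Fst for every unordered deme pair in lexicographic
#' (configuration-order) pair order. For the default 13-deme layout this is
#' 109 entries.
#'
#' @param deme_ids Character vector of deme ids in configuration order.
#' @return Character vector of statistic names.
#' @export
summary_vector_names <- function(deme_ids) {
  pairs <- utils::combn(deme_ids, 2)
  c(paste0("S_", deme_ids), "S_mean", "S_sd", "S_total",
    paste0("pi_", deme_ids), "pi_mean", "pi_sd",
    paste0("fst_", pairs[1, ], "_", pairs[2, ]))
}

#' Compute the ordered summary-statistic vector
#'
#' Assembles the canonical statistic vector used by the ABC reference table:
#' segregating sites per deme, their mean, population SD (denominator `d`)
#' and total; per-site nucleotide diversity per deme with mean and SD; and
#' Hudson Fst for every unordered deme pair. Order follows
#' [summary_vector_names()] with demes in `deme_order` (defaulting to first
#' appearance in the alignment); the order is fixed — no silent reordering.
#'
#' @inheritParams pairwise_fst
#' @param deme_order Character vector fixing the deme order; must cover every
#'   deme present. Samples with a deme outside `deme_order` are an error.
#' @return One-row tibble with the named statistics, carrying the deme order
#'   in attribute `deme_order`.
#' @examples
#' geno <- rbind(A = c("A", "A", "A"), B = c("A", "A", "T"),
#'               C = c("T", "T", "A"), D = c("T", "T", "T"))
#' aln <- haplotype_alignment(geno, deme = c("p1", "p1", "p2", "p2"),
#'                            seq_length = 3)
#' summarize_alignment(aln)
#' @export
summarize_alignment <- function(aln, deme_order = NULL,
                                clamp_negative = FALSE) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  present <- unique(aln$samples$deme_id)
  if (is.null(deme_order)) deme_order <- present
  missing_d <- setdiff(present, deme_order)
  if (length(missing_d))
    stop("sample with no deme assignment in the layout: deme(s) ",
         paste(missing_d, collapse = ", "), " not in deme_order",
         call. = FALSE)
  d <- length(deme_order)
  if (d < 2)
    stop("summary vector requires at least two demes", call. = FALSE)
  geno <- aln$genotypes
  L <- aln$seq_length
  dmf <- factor(aln$samples$deme_id, levels = deme_order)
  n_d <- as.integer(table(dmf))
  if (any(n_d == 0))
    stop("deme_order lists deme(s) with no samples in the alignment: ",
         paste(deme_order[n_d == 0], collapse = ", "), call. = FALSE)
  n <- nrow(geno)
  s_cols <- ncol(geno)

  if (s_cols > 0) {
    # fast path for simulated 0/1 matrices: one rowsum gives derived counts
    binary <- is.numeric(geno) &&
      { rg <- range(geno); rg[1] >= 0 && rg[2] <= 1 &&
          all(rg == floor(rg)) }
    counts <- if (binary) {
      c1 <- rowsum(geno, dmf)[deme_order, , drop = FALSE]
      list(n_d - c1, c1)
    } else {
      lapply(unique(as.vector(geno)), function(s) {
        rowsum((geno == s) + 0L, dmf)[deme_order, , drop = FALSE]
      })
    }
    maxc <- Reduce(pmax, counts)
    S_deme <- as.integer(rowSums(maxc < n_d & n_d > 1))
    # M[a, b] = sum over sites and states of c_a * c_b; its diagonal gives
    # the within-deme sum of squared counts, the off-diagonal the
    # between-deme identity term of Hudson's Hb
    M <- Reduce(`+`, lapply(counts, tcrossprod))
    within_pair_sum <- (n_d^2 * s_cols - diag(M)) / 2
    pi_deme <- ifelse(n_d > 1, within_pair_sum / choose(n_d, 2) / L, 0)
    tot <- lapply(counts, colSums)
    S_total <- sum(Reduce(pmax, tot) < n)
    pairs <- utils::combn(d, 2)
    fst <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      nab <- n_d[a] * n_d[b]
      hb <- (nab * s_cols - M[a, b]) / nab / L
      fst[k] <- if (hb == 0) 0 else 1 - (pi_deme[a] + pi_deme[b]) / 2 / hb
      if (clamp_negative) fst[k] <- max(fst[k], 0)
    }
  } else {
    S_deme <- integer(d)
    pi_deme <- numeric(d)
    S_total <- 0L
    fst <- numeric(d * (d - 1) / 2)
  }

  vals <- c(S_deme, mean(S_deme), sd_pop(S_deme), S_total,
            pi_deme, mean(pi_deme), sd_pop(pi_deme), fst)
  out <- tibble::as_tibble(stats::setNames(as.list(vals),
                                           summary_vector_names(deme_order)))
  attr(out, "deme_order") <- deme_order
  attr(out, "single_sample_demes") <- deme_order[n_d == 1]
  out
}

# SD with denominator d (population SD), deterministic across d >= 1
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Write a summary vector as a single-row named CSV
#'
#' @param summary One-row tibble from [summarize_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  readr::write_csv(summary, path)
  invisible(path)
}
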