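#' Default study layout
#'
#' The sampling design the packaged defaults emulate: 13 demes over 5
#' clades, 113 mitogenomes in total (59 ancient across 12 dated demes plus
#' 54 modern in the present-day deme), sampling ages spanning 0--50 ka BP,
#' and a sequence length of ~16.3 kb.
#'
#' @param config A `coal_config`; the layout is its deme table plus the
#'   clock's sequence length.
#' @return Object of class `study_layout`: list with `demes` (tibble
#'   `deme_id`, `clade`, `age_years_bp`, `n_samples`), `n_total`,
#'   `seq_length`.
#' @examples
#' default_layout()
#' @export
default_layout <- function(config = default_model_config()) {
  structure(list(
    demes = config$demes[, c("deme_id", "clade", "age_years_bp",
                             "n_samples")],
    n_total = as.integer(sum(config$demes$n_samples)),
    seq_length = config$clock$seq_length),
    class = "study_layout")
}

#' @export
print.study_layout <- function(x, ...) {
  cat("<study_layout> ", nrow(x$demes), " demes, ",
      length(unique(x$demes$clade)), " clades, ", x$n_total,
      " samples, L = ", x$seq_length, "\n", sep = "")
  invisible(x)
}

#' Encode an infinite-sites alignment as nucleotide sequences
#'
#' Embeds the 0/1 variant matrix into a monomorphic reference background:
#' every position of the `L`-site sequence is the reference base `"A"`,
#' and derived alleles are written as `"T"` at their segregating positions.
#' This documented encoding produces valid nucleotide FASTA while keeping
#' all summary statistics identical to the binary representation.
#'
#' @param aln A [haplotype_alignment()] with 0/1 genotypes.
#' @return Character vector of sequences (one per sample, names =
#'   sample ids).
#' @export
as_nucleotide_sequences <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  L <- aln$seq_length
  n <- nrow(aln$genotypes)
  out <- character(n)
  base <- rep("A", L)
  for (i in seq_len(n)) {
    s <- base
    s[aln$positions[aln$genotypes[i, ] == 1]] <- "T"
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- aln$samples$sample_id
  out
}

#' Generate an observed-style synthetic dataset
#'
#' Simulates one genealogy plus mutations under a scenario and writes the
#' three observed-data files the pipeline consumes: a FASTA alignment
#' (wrapped at 80 columns), a metadata TSV (`sample_id`, `deme_id`, `clade`,
#' `age_years_bp` with integer ages), and a ground-truth JSON recording the
#' generating scenario, the drawn parameters and the seed — sufficient to
#' regenerate the dataset bit-identically.
#'
#' @param model_name One of the four scenario names.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; required for regenerability.
#' @param config A `coal_config`.
#' @param params Optional `model_params` to use instead of a fresh prior
#'   draw (e.g. to pin bottleneck severities).
#' @param basename Stem for the three file names.
#' @return Object of class `synthetic_dataset`: list with `paths` (named:
#'   `fasta`, `metadata`, `truth`), `model`, `params`, `seed`, and the
#'   simulated `alignment`.
#' @examples
#' \donttest{
#' ds <- generate_observed("constant", dir = tempdir(), seed = 1)
#' ds$paths
#' }
#' @export
generate_observed <- function(model_name, dir, seed,
                              config = default_model_config(),
                              params = NULL, basename = "synthetic") {
  if (missing(seed) || !is.numeric(seed))
    stop("seed is required", call. = FALSE)
  model <- build_model(model_name, config)
  set.seed(as.integer(seed))
  if (is.null(params)) params <- draw_params(model)
  gen <- simulate_genealogy(model, params)
  aln <- drop_mutations(gen)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta    = file.path(dir, paste0(basename, ".fasta")),
             metadata = file.path(dir, paste0(basename, "_metadata.tsv")),
             truth    = file.path(dir, paste0(basename, "_truth.json")))

  seqs <- as_nucleotide_sequences(aln)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              paths[["fasta"]], width = 80)

  clade_of <- stats::setNames(config$demes$clade, config$demes$deme_id)
  meta <- tibble::tibble(
    sample_id = aln$samples$sample_id,
    deme_id = aln$samples$deme_id,
    clade = unname(clade_of[aln$samples$deme_id]),
    age_years_bp = as.integer(round(gen$samples$age_years_bp)))
  readr::write_tsv(meta, paths[["metadata"]])

  truth <- list(
    model = model_name,
    seed = as.integer(seed),
    params = list(
      bottlenecks = as.list(params$bottlenecks),
      sizes = as.list(params$sizes)),
    layout = list(n_demes = nrow(config$demes),
                  n_samples = sum(config$demes$n_samples),
                  seq_length = config$clock$seq_length))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(paths = paths, model = model_name, params = params,
                 seed = as.integer(seed), alignment = aln),
            class = "synthetic_dataset")
}

#' Read an observed dataset (FASTA + metadata TSV)
#'
#' Reads a multi-sequence alignment and its sample metadata into a
#' [haplotype_alignment()]. Only polymorphic columns are stored (with their
#' positions); the full alignment length is kept as `seq_length` so per-site
#' statistics are unaffected. Samples are ordered as in the metadata; FASTA
#' record names must match `sample_id`.
#'
#' @param fasta_path Path to the FASTA alignment.
#' @param metadata_path Path to the TSV with columns `sample_id`, `deme_id`,
#'   `clade`, `age_years_bp`.
#' @return A `haplotype_alignment` with attribute `metadata` (the tibble).
#' @export
read_observed <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            sample_id = "c", deme_id = "c", clade = "c",
                            age_years_bp = "d"))
  need <- c("sample_id", "deme_id", "clade", "age_years_bp")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing_s <- setdiff(meta$sample_id, names(seqs))
  if (length(missing_s))
    stop("metadata sample(s) absent from FASTA: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1)
    stop("FASTA records have unequal lengths; an alignment is required",
         call. = FALSE)
  m <- as.matrix(seqs[meta$sample_id])
  L <- ncol(m)
  ref <- matrix(m[1L, ], nrow(m), L, byrow = TRUE)
  poly <- which(colSums(m != ref) > 0)
  aln <- haplotype_alignment(m[, poly, drop = FALSE],
                             deme = meta$deme_id,
                             seq_length = L,
                             positions = poly,
                             sample_ids = meta$sample_id)
  attr(aln, "metadata") <- meta
  aln
}
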