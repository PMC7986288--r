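#' Read and write sample metadata
#'
#' Metadata binds every sample to its chamber, treatment, replicate,
#' experiment and sampling time. Required TSV columns: `sample_id`,
#' `chamber_id`, `treatment`, `replicate`, `experiment_id`, `time_h`.
#' Unknown extra columns are dropped silently; missing required columns are
#' an error. The `phase` column is (re)derived from `time_h` via
#' [assign_phase()] so it can never disagree with the windowing rule.
#'
#' @param path File path to a TSV.
#' @param window Exposure window passed to [assign_phase()].
#' @return Tibble with the six required columns plus `phase`.
#' @export
read_metadata <- function(path, window = phase_windows()$treatment) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  required <- c("sample_id", "chamber_id", "treatment", "replicate",
                "experiment_id", "time_h")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Metadata is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  raw <- raw[required]
  time_h <- suppressWarnings(as.numeric(raw$time_h))
  if (anyNA(time_h)) {
    abort(paste0("Non-numeric time_h for sample ",
                 raw$sample_id[is.na(time_h)][1]))
  }
  replicate <- suppressWarnings(as.integer(raw$replicate))
  if (anyNA(replicate) || any(replicate < 1)) {
    abort("`replicate` must be an integer >= 1 for every sample.")
  }
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0("Duplicate sample id: ",
                 raw$sample_id[duplicated(raw$sample_id)][1]))
  }
  raw$replicate <- replicate
  raw$time_h <- time_h
  raw$phase <- assign_phase(time_h, window)
  raw
}

#' @rdname read_metadata
#' @param metadata Metadata tibble to write.
#' @return `write_metadata()`: `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(dplyr::select(metadata, -dplyr::any_of("phase")), path)
  invisible(path)
}

#' Read a rooted phylogenetic tree from Newick
#'
#' Thin wrapper over [ape::read.tree()] with validation: the tree must
#' parse, carry branch lengths, and have non-negative branch lengths.
#' Unrooted trees are accepted here; UniFrac computations midpoint-root
#' them on entry.
#'
#' @param path File path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) abort(paste0(
                     "Newick parse error in ", path, ": ",
                     conditionMessage(e))))
  if (is.null(tree)) abort(paste0("Newick parse error in ", path))
  if (is.null(tree$edge.length)) {
    abort("Tree has no branch lengths; UniFrac requires them.")
  }
  if (any(tree$edge.length < 0)) abort("Negative branch length in tree.")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("Duplicate leaf label: ",
                 tree$tip.label[duplicated(tree$tip.label)][1]))
  }
  tree
}

#' Read reporter-assay plate readings
#'
#' CSV with columns `sample_id`, `analyte` (`LPS` or `FliC`),
#' `dilution_factor` (positive), `od620`. Within each sample x analyte
#' series the dilution factors must be distinct; readings are returned
#' sorted by increasing dilution.
#'
#' @param path File path to a CSV.
#' @return Tibble of plate readings.
#' @export
read_plate_readings <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", analyte = "c", dilution_factor = "d", od620 = "d"))
  if (!all(c("sample_id", "analyte", "dilution_factor", "od620") %in%
           names(raw))) {
    abort("Plate readings need columns sample_id, analyte, dilution_factor, od620.")
  }
  if (any(!is.finite(raw$od620))) abort("Non-finite OD620 reading.")
  if (any(raw$dilution_factor <= 0)) abort("Dilution factors must be positive.")
  dup <- raw |>
    dplyr::count(.data$sample_id, .data$analyte, .data$dilution_factor) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Repeated dilution factor for sample ", dup$sample_id[1]))
  }
  dplyr::arrange(raw, .data$sample_id, .data$analyte, .data$dilution_factor)
}

#' Read a qPCR Cq table
#'
#' CSV with columns `sample_id`, `cq` and, for standard rows, a
#' `log10_quantity` column giving the known log10 template quantity
#' (blank/NA for unknowns). Cq values must be finite and positive.
#'
#' @param path File path to a CSV.
#' @return Tibble with columns `sample_id`, `cq`, `log10_quantity`.
#' @export
read_cq_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", cq = "d", .default = "d"))
  if (!all(c("sample_id", "cq") %in% names(raw))) {
    abort("Cq table needs columns sample_id and cq.")
  }
  if (any(!is.finite(raw$cq)) || any(raw$cq <= 0)) {
    abort("Cq values must be finite and > 0.")
  }
  if (!"log10_quantity" %in% names(raw)) raw$log10_quantity <- NA_real_
  raw[c("sample_id", "cq", "log10_quantity")]
}

#' Read and write FASTQ reads as a tibble
#'
#' Reads are represented as a tibble with columns `id`, `sequence` and
#' `quality` (Phred+33 encoded string of the same length as the sequence).
#' IO goes through Biostrings.
#'
#' @param path File path to an (uncompressed) FASTQ file.
#' @return `read_fastq()`: tibble of reads.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("FASTQ IO requires the `Biostrings` package.")
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(id = names(x),
         sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' @rdname read_fastq
#' @param reads Tibble of reads with columns `id`, `sequence`, `quality`.
#' @return `write_fastq()`: `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("FASTQ IO requires the `Biostrings` package.")
  }
  if (nrow(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    abort("Sequence and quality strings must have equal length.")
  }
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Phred+33 helpers for per-base qualities
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return `phred_scores()`: list of integer vectors of per-base scores.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}
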