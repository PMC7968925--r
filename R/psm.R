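#' PSM count matrix with sample metadata
#'
#' Container for a proteins x samples matrix of peptide-spectrum-match (PSM)
#' counts, the semi-quantitative abundance unit of spectral-count proteomics,
#' together with the per-sample condition (`"bait"` or `"control"`) and
#' replicate number. Counts are nonnegative integers; missing observations are
#' represented as `NA` until [impute_missing()] sets them to 0.
#'
#' @param counts numeric matrix, proteins in rows (rownames = protein symbols),
#'   samples in columns (colnames = sample ids). Nonnegative; `NA` allowed for
#'   not-yet-imputed cells.
#' @param condition character vector, one of `"bait"`/`"control"` per sample,
#'   in column order.
#' @param replicate positive integer vector, replicate id per sample.
#' @return An object of class `psm_matrix`: a list with elements `counts`,
#'   `condition`, `replicate`.
#' @export
psm_matrix <- function(counts, condition, replicate) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry protein rownames and sample colnames")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop("duplicate protein ids: ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids")
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be nonnegative")
  condition <- as.character(condition)
  replicate <- as.integer(replicate)
  if (length(condition) != ncol(counts) || length(replicate) != ncol(counts))
    stop("condition/replicate must have one entry per sample column")
  bad <- setdiff(unique(condition), c("bait", "control"))
  if (length(bad))
    stop("condition labels must be 'bait' or 'control', got: ",
         paste(bad, collapse = ", "))
  if (!all(c("bait", "control") %in% condition))
    stop("both 'bait' and 'control' conditions need at least one sample")
  if (any(replicate < 1L))
    stop("replicate ids must be positive integers")
  structure(
    list(counts = counts, condition = condition, replicate = replicate),
    class = "psm_matrix"
  )
}

#' @export
print.psm_matrix <- function(x, ...) {
  cat(sprintf("psm_matrix: %d proteins x %d samples (%d bait, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "bait"), sum(x$condition == "control")))
  if (anyNA(x$counts))
    cat(sprintf("  %d missing cells (not yet imputed)\n", sum(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.psm_matrix <- function(x) dim(x$counts)

bait_cols <- function(psm) which(psm$condition == "bait")
control_cols <- function(psm) which(psm$condition == "control")

#' Read a PSM table with its sample design
#'
#' The PSM table is tab-separated with a `protein_id` column (first column)
#' and one numeric column per sample. The design maps each sample column to a
#' condition and replicate; it may be given as a data frame with columns
#' `sample_id`, `condition`, `replicate`, or as the path of a two-column TSV
#' whose second column is `condition` or `condition:replicate` (replicates
#' default to 1, 2, ... within condition when omitted).
#'
#' @param path path of the PSM TSV.
#' @param design data frame or path of the design TSV.
#' @return A [psm_matrix()]. Empty cells in the table are read as `NA`
#'   (missing observation); non-numeric text in a count cell is an error.
#' @export
read_psm_table <- function(path, design) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"))
  if (ncol(tab) < 2L)
    stop("PSM table needs a protein_id column plus at least one sample column")
  ids <- tab[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein ids in ", path, ": ", paste(dup, collapse = ", "))
  design <- as_design(design)
  missing_samples <- setdiff(design$sample_id, colnames(tab)[-1L])
  if (length(missing_samples))
    stop("samples in design absent from PSM table: ",
         paste(missing_samples, collapse = ", "))
  raw <- as.matrix(tab[, design$sample_id, drop = FALSE])
  counts <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- !is.na(raw) & is.na(counts)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unparseable count '%s' (protein %s, sample %s)",
                 raw[bad][1L], ids[i[1L]], design$sample_id[i[2L]]))
  }
  if (any(counts != round(counts), na.rm = TRUE))
    stop("PSM counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(ids, design$sample_id)
  psm_matrix(counts, design$condition, design$replicate)
}

as_design <- function(design) {
  if (is.character(design) && length(design) == 1L) {
    d <- utils::read.delim(design, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
    if (ncol(d) < 2L) stop("design TSV needs sample_id and condition columns")
    spl <- strsplit(d[[2L]], ":", fixed = TRUE)
    cond <- vapply(spl, `[[`, "", 1L)
    rep_ <- vapply(spl, function(z) if (length(z) > 1L) z[[2L]] else NA_character_, "")
    design <- data.frame(sample_id = d[[1L]], condition = cond,
                         replicate = suppressWarnings(as.integer(rep_)))
  }
  design <- as.data.frame(design)
  if (!all(c("sample_id", "condition") %in% names(design)))
    stop("design needs sample_id and condition")
  if (is.null(design$replicate) || anyNA(design$replicate)) {
    design$replicate <- stats::ave(seq_len(nrow(design)), design$condition,
                                   FUN = seq_along)
  }
  design
}

#' Write a PSM matrix and its design as TSV files
#'
#' @param psm a [psm_matrix()].
#' @param path output path of the PSM table.
#' @param design_path optional path for the companion design TSV
#'   (`sample_id`, `condition:replicate`).
#' @return `path`, invisibly. `NA` cells are written as empty strings so the
#'   missing/zero distinction survives a round trip.
#' @export
write_psm_table <- function(psm, path, design_path = NULL) {
  df <- data.frame(protein_id = rownames(psm$counts), psm$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (!is.null(design_path)) {
    dd <- data.frame(sample_id = colnames(psm$counts),
                     condition = paste(psm$condition, psm$replicate, sep = ":"))
    utils::write.table(dd, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
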