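#' Diploid microsatellite genotype matrix
#'
#' The central data container of the package: unordered diploid allele-state
#' pairs per accession x locus, stored as two parallel numeric matrices, plus
#' per-accession metadata (population, geographic region, wild/cultivated
#' status) and a per-locus table (motif length, coding).
#'
#' Allele states are positive numbers: fragment sizes in base pairs
#' (`coding = "size_bp"`) or repeat units (`coding = "repeat_count"`, possibly
#' fractional for off-ladder single-nucleotide-indel alleles). A missing call
#' is `NA` in both matrices; half-calls are not allowed and are normalised to
#' fully missing.
#'
#' @param a1,a2 numeric matrices (accessions x loci) of allele states;
#'   `NA` marks missing calls.
#' @param loci data frame with columns `name`, `motif_length` and `coding`
#'   (one of `"size_bp"`, `"repeat_count"`); defaults to dinucleotide
#'   size-coded loci named from `colnames(a1)`.
#' @param metadata data frame with columns `accession`, `population`,
#'   `region`, `status` (status in `wild`, `cultivated`, `relative`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, loci = NULL, metadata = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == dim(a2))) stop("a1 and a2 must have identical dimensions")
  n <- nrow(a1); L <- ncol(a1)
  if (n == 0 || L == 0) stop("empty genotype matrix")
  if (is.null(rownames(a1))) rownames(a1) <- paste0("acc", seq_len(n))
  if (is.null(colnames(a1))) colnames(a1) <- paste0("L", seq_len(L))
  dimnames(a2) <- dimnames(a1)
  # normalise half-calls to fully missing
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_real_; a2[miss] <- NA_real_
  if (any(!miss & (a1 <= 0 | a2 <= 0))) stop("allele states must be positive")
  if (is.null(loci)) {
    loci <- data.frame(name = colnames(a1), motif_length = 2L,
                       coding = "size_bp", stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (!all(c("name", "motif_length", "coding") %in% names(loci)))
    stop("loci must have columns name, motif_length, coding")
  if (anyDuplicated(loci$name)) stop("locus names must be unique")
  if (any(loci$motif_length < 1)) stop("motif_length must be >= 1")
  if (!all(loci$coding %in% c("size_bp", "repeat_count")))
    stop("coding must be 'size_bp' or 'repeat_count'")
  if (nrow(loci) != L) stop("loci table does not match the number of columns")
  if (is.null(metadata)) {
    metadata <- data.frame(accession = rownames(a1), population = "pop1",
                           region = "unknown", status = "wild",
                           stringsAsFactors = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("accession", "population", "region", "status") %in% names(metadata)))
    stop("metadata must have columns accession, population, region, status")
  idx <- match(rownames(a1), metadata$accession)
  if (anyNA(idx)) {
    stop("metadata missing for accession(s): ",
         paste(rownames(a1)[is.na(idx)][seq_len(min(5, sum(is.na(idx))))],
               collapse = ", "))
  }
  metadata <- metadata[idx, , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(a1 = a1, a2 = a2, loci = loci, metadata = metadata),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$a1), "accessions x", ncol(x$a1), "loci\n")
  cat("  populations:", length(unique(x$metadata$population)),
      " regions:", length(unique(x$metadata$region)),
      " missing:", sprintf("%.1f%%", 100 * mean(is.na(x$a1))), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$a1)

n_accessions <- function(gm) nrow(gm$a1)
n_loci <- function(gm) ncol(gm$a1)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i accession index (integer, logical or accession ids).
#' @param j locus index (integer, logical or locus names).
#' @param ... unused.
#' @return A `genotype_matrix` restricted to the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_len(ncol(x$a1))
  if (is.character(i)) i <- match(i, rownames(x$a1))
  if (is.character(j)) j <- match(j, x$loci$name)
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  loci = x$loci[j, , drop = FALSE],
                  metadata = x$metadata[i, , drop = FALSE])
}

#' Resolve a grouping of accessions
#'
#' @param gm a [genotype_matrix()].
#' @param by `"population"`, `"region"`, `"status"`, or a vector/factor of
#'   labels (one per accession, optionally named by accession id).
#' @return A character vector of group labels, one per accession.
#' @export
group_labels <- function(gm, by = "population") {
  if (is.character(by) && length(by) == 1 &&
      by %in% c("population", "region", "status")) {
    return(gm$metadata[[by]])
  }
  if (length(by) != n_accessions(gm))
    stop("grouping must name every accession")
  if (!is.null(names(by))) by <- by[rownames(gm$a1)]
  as.character(by)
}
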