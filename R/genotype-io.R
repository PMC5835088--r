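#' Read a GenePop file
#'
#' Parses the GenePop text dialect: a title line, locus names (one per line
#' or comma-separated on one line), population blocks separated by lines
#' equal to "Pop" (case-insensitive), and individual lines
#' `id , g1 g2 ...` where each genotype is `2 * allele_digits` digits and a
#' zero allele codes a missing call.
#'
#' @param path path to a GenePop file.
#' @param allele_digits 2 or 3 digits per allele.
#' @param pop_names `"last_id"` (GenePop convention: a population is named
#'   after the id of its last individual) or `"sequential"` (`pop1..popN`).
#' @return A [genotype_matrix()]; regions and statuses are set to
#'   `"unknown"`/`"wild"` placeholders since GenePop carries no metadata.
#' @export
read_genepop <- function(path, allele_digits = 3,
                         pop_names = c("last_id", "sequential")) {
  pop_names <- match.arg(pop_names)
  if (!allele_digits %in% c(2, 3)) stop("allele_digits must be 2 or 3")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a GenePop file: too few lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found")
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L == 0) stop("no locus names declared")

  blocks <- split(seq(first_pop, length(lines)),
                  cumsum(is_pop[seq(first_pop, length(lines))]))
  ids <- character(); pops <- character()
  rows1 <- list(); rows2 <- list()
  w <- allele_digits
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]][-1]  # drop the Pop line itself
    if (length(idx) == 0) stop("empty Pop block ", b)
    bid <- character(length(idx))
    for (r in seq_along(idx)) {
      ln <- lines[idx[r]]
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2) stop("malformed individual line: ", ln)
      id <- trimws(parts[1])
      gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
      gts <- gts[nzchar(gts)]
      if (length(gts) != L)
        stop("individual '", id, "' has ", length(gts),
             " genotypes for ", L, " declared loci")
      if (any(nchar(gts) != 2 * w))
        stop("malformed genotype width for individual '", id, "'")
      if (any(grepl("[^0-9]", gts)))
        stop("non-numeric genotype for individual '", id, "'")
      g1 <- as.numeric(substr(gts, 1, w))
      g2 <- as.numeric(substr(gts, w + 1, 2 * w))
      g1[g1 == 0] <- NA; g2[g2 == 0] <- NA
      bid[r] <- id
      rows1[[length(rows1) + 1]] <- g1
      rows2[[length(rows2) + 1]] <- g2
    }
    pname <- if (pop_names == "last_id") bid[length(bid)] else paste0("pop", b)
    ids <- c(ids, bid)
    pops <- c(pops, rep(pname, length(bid)))
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  rownames(a1) <- ids
  colnames(a1) <- loci
  meta <- data.frame(accession = ids, population = pops, region = "unknown",
                     status = "wild", stringsAsFactors = FALSE)
  genotype_matrix(a1, a2,
                  loci = data.frame(name = loci, motif_length = 2L,
                                    coding = "size_bp", stringsAsFactors = FALSE),
                  metadata = meta)
}

#' Write a GenePop file
#'
#' Accessions are grouped into Pop blocks by their population id (in order
#' of first appearance). `read_genepop(write_genepop(gm))` reproduces calls
#' and population grouping.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param allele_digits 2 or 3; all allele states must be integers below
#'   `10^allele_digits`.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path, allele_digits = 3,
                          title = "cherrydemog export") {
  if (!allele_digits %in% c(2, 3)) stop("allele_digits must be 2 or 3")
  if (n_accessions(gm) == 0 || n_loci(gm) == 0)
    stop("cannot write an empty genotype matrix")
  vals <- c(gm$a1, gm$a2)
  vals <- vals[!is.na(vals)]
  if (any(vals != round(vals))) stop("GenePop requires integer allele states")
  if (any(vals >= 10^allele_digits))
    stop("allele state too wide for ", allele_digits, "-digit GenePop output")
  w <- allele_digits
  fmt <- function(x) {
    x[is.na(x)] <- 0
    sprintf(paste0("%0", w, "d"), as.integer(x))
  }
  out <- c(title, gm$loci$name)
  pops <- gm$metadata$population
  for (p in unique(pops)) {
    out <- c(out, "Pop")
    for (i in which(pops == p)) {
      gts <- paste0(fmt(gm$a1[i, ]), fmt(gm$a2[i, ]))
      out <- c(out, paste(rownames(gm$a1)[i], ",", paste(gts, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a delimited genotype table with metadata
#'
#' One row per accession; the first column holds accession ids and every
#' locus contributes two adjacent allele-size columns. Blank or `NA` cells
#' are missing. Metadata maps each accession to a population, region and
#' status; accessions absent from the metadata are rejected.
#'
#' @param path genotype table (CSV, or TSV when the file has tab separators).
#' @param metadata_path metadata table with columns `accession`,
#'   `population`, `region`, `status`.
#' @param motif_length per-locus motif lengths (recycled).
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, metadata_path, motif_length = 2L) {
  sep <- if (any(grepl("\t", readLines(path, n = 2)))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate accession id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gcols <- tab[, -1, drop = FALSE]
  if (ncol(gcols) %% 2 != 0) stop("odd number of allele columns")
  L <- ncol(gcols) / 2
  a1 <- as.matrix(gcols[, 2 * seq_len(L) - 1, drop = FALSE])
  a2 <- as.matrix(gcols[, 2 * seq_len(L), drop = FALSE])
  mode(a1) <- "numeric"; mode(a2) <- "numeric"
  lnames <- sub("[._ ]?[ab12]$", "", colnames(gcols)[2 * seq_len(L) - 1])
  if (anyDuplicated(lnames)) lnames <- paste0("L", seq_len(L))
  rownames(a1) <- ids
  colnames(a1) <- lnames
  msep <- if (any(grepl("\t", readLines(metadata_path, n = 2)))) "\t" else ","
  meta <- utils::read.table(metadata_path, header = TRUE, sep = msep,
                            stringsAsFactors = FALSE)
  missing_meta <- setdiff(ids, meta$accession)
  if (length(missing_meta))
    stop("metadata missing for accession(s): ",
         paste(missing_meta, collapse = ", "))
  genotype_matrix(a1, a2,
                  loci = data.frame(name = lnames,
                                    motif_length = rep_len(as.integer(motif_length), L),
                                    coding = "size_bp", stringsAsFactors = FALSE),
                  metadata = meta)
}

#' Filter loci and accessions by missingness
#'
#' Loci whose missing fraction strictly exceeds `max_locus_missing` are
#' removed first; accession missing fractions are then recomputed over the
#' retained loci and accessions strictly above `max_accession_missing` are
#' removed. Both thresholds are strict ("more than"), so a boundary value is
#' retained.
#'
#' @param gm a [genotype_matrix()].
#' @param max_locus_missing,max_accession_missing proportions in (0, 1].
#' @return A list with the filtered `gm` and a `report`
#'   (class `missingness_report`) recording per-locus and per-accession
#'   missing fractions and removal lists for both passes.
#' @export
filter_missingness <- function(gm, max_locus_missing = 0.30,
                               max_accession_missing = 0.25) {
  stopifnot(max_locus_missing > 0, max_locus_missing <= 1,
            max_accession_missing > 0, max_accession_missing <= 1)
  miss <- is.na(gm$a1)
  locus_frac <- colMeans(miss)
  drop_loci <- which(locus_frac > max_locus_missing)
  if (length(drop_loci) == ncol(miss)) stop("all loci removed by filter")
  keep_l <- setdiff(seq_len(ncol(miss)), drop_loci)
  miss2 <- miss[, keep_l, drop = FALSE]
  acc_frac <- rowMeans(miss2)
  drop_acc <- which(acc_frac > max_accession_missing)
  if (length(drop_acc) == nrow(miss2)) stop("all accessions removed by filter")
  keep_a <- setdiff(seq_len(nrow(miss2)), drop_acc)
  report <- structure(list(
    locus_missing = locus_frac,
    removed_loci = colnames(gm$a1)[drop_loci],
    accession_missing = acc_frac,
    removed_accessions = rownames(gm$a1)[drop_acc],
    thresholds = c(locus = max_locus_missing, accession = max_accession_missing)
  ), class = "missingness_report")
  list(gm = gm[keep_a, keep_l], report = report)
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("missingness filter: removed", length(x$removed_loci), "loci and",
      length(x$removed_accessions), "accessions\n")
  invisible(x)
}

#' Convert fragment sizes to repeat units
#'
#' Allele states become `(size - min_size_at_locus) / motif_length + 1`.
#' Sizes that are not a whole number of motifs above the locus minimum
#' (single-nucleotide-indel alleles) keep their fractional position and so
#' remain distinct states off the repeat ladder. Matrices already coded in
#' repeat units pass through unchanged.
#'
#' @param gm a [genotype_matrix()] with `size_bp` coded loci.
#' @return A `genotype_matrix` with `coding = "repeat_count"`.
#' @export
to_repeat_units <- function(gm) {
  if (all(gm$loci$coding == "repeat_count")) return(gm)
  if (anyNA(gm$loci$motif_length)) stop("motif_length missing for some locus")
  a1 <- gm$a1; a2 <- gm$a2
  for (l in seq_len(ncol(a1))) {
    if (gm$loci$coding[l] == "repeat_count") next
    m <- gm$loci$motif_length[l]
    mn <- suppressWarnings(min(c(a1[, l], a2[, l]), na.rm = TRUE))
    if (!is.finite(mn)) next
    a1[, l] <- (a1[, l] - mn) / m + 1
    a2[, l] <- (a2[, l] - mn) / m + 1
  }
  loci <- gm$loci
  loci$coding <- "repeat_count"
  genotype_matrix(a1, a2, loci = loci, metadata = gm$metadata)
}
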