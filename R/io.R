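#' Read a genotype dosage table
#'
#' Reads minor-allele dosages either from the canonical TSV dialect (first
#' column `sample_id`, remaining columns rsIDs, cells in `{0, 1, 2, NA}`) or
#' from a VCF 4.x file, whose diploid GT fields are converted to counts of the
#' ALT allele. VCF dosages are oriented to the ALT allele as written; run
#' [orient_minor_allele()] downstream to re-orient to the sample minor allele.
#'
#' @param path Path to the genotype file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param variants For `dialect = "tsv"`, a [variant_info()] table covering
#'   every rsID in the file (column order of the file is kept). Ignored for
#'   VCF, where the annotation is taken from the VCF records themselves
#'   (ALT as minor_allele, REF as major_allele; `gene` from the `GENE` INFO
#'   key when present, otherwise `"."`).
#'
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf"), variants = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") read_genotypes_tsv(path, variants) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path, variants) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (names(raw)[1] != "sample_id") stop("first column must be 'sample_id'")
  rsids <- names(raw)[-1]
  if (anyDuplicated(rsids)) {
    stop("duplicated rsID column(s): ",
         paste(unique(rsids[duplicated(rsids)]), collapse = ", "))
  }
  dos <- matrix(NA_integer_, nrow(raw), length(rsids),
                dimnames = list(raw$sample_id, rsids))
  for (j in seq_along(rsids)) {
    cell <- raw[[j + 1L]]
    ok <- cell %in% c("0", "1", "2", "NA", "")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("malformed dosage value '%s' at row %d (sample %s), column %s",
                   cell[i], i, raw$sample_id[i], rsids[j]))
    }
    num <- !cell %in% c("NA", "")
    col <- rep(NA_integer_, length(cell))
    col[num] <- as.integer(cell[num])
    dos[, j] <- col
  }
  if (is.null(variants)) {
    variants <- variant_info(rsid = rsids, chrom = rep("1", length(rsids)),
                             pos = seq_along(rsids), gene = ".",
                             minor_allele = "A", major_allele = "G")
  } else {
    missing_ann <- setdiff(rsids, variants$rsid)
    if (length(missing_ann)) {
      stop("variant annotation missing for: ", paste(missing_ann, collapse = ", "))
    }
    variants <- variants[match(rsids, variants$rsid), , drop = FALSE]
  }
  genotype_matrix(dos, variants, samples = raw$sample_id)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  fx <- matrix(fx, ncol = ncol(fx), dimnames = dimnames(fx)) # 1-row guard
  rsid <- fx[, "ID"]
  if (anyDuplicated(rsid)) {
    stop("duplicated rsID(s) in VCF: ",
         paste(unique(rsid[duplicated(rsid)]), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count ALT alleles per genotype; accept phased or unphased separators
  count_alt <- function(g) {
    if (is.na(g) | g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  gene <- vcfR::extract.info(vcf, element = "GENE")
  if (is.null(gene)) gene <- rep(".", length(rsid))
  gene[is.na(gene)] <- "."
  variants <- variant_info(
    rsid = rsid, chrom = sub("^chr", "", fx[, "CHROM"]),
    pos = as.integer(fx[, "POS"]), gene = gene,
    minor_allele = fx[, "ALT"], major_allele = fx[, "REF"]
  )
  genotype_matrix(t(dos), variants, samples = colnames(gt))
}

#' Read a variant annotation table
#'
#' TSV with columns `rsid, chrom, pos, gene, minor_allele, major_allele`.
#'
#' @param path File path.
#' @return A validated [variant_info()] tibble.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, colClasses = "character")
  need <- c("rsid", "chrom", "pos", "gene", "minor_allele", "major_allele")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  variant_info(x$rsid, x$chrom, as.integer(x$pos), x$gene,
               x$minor_allele, x$major_allele)
}

# questionnaire category -> fixed risk coding (1 = light pigmentation /
# poor tolerance). Numeric 0/1 are accepted as already coded.
TRAIT_CODING <- list(
  eye        = c("blue" = 1, "green" = 1, "brown" = 0, "black" = 0),
  hair       = c("blond" = 1, "red" = 1, "brown" = 0, "black" = 0),
  skin       = c("fair" = 1, "dark" = 0),
  naevi      = c(">=50" = 1, "<50" = 0),
  lentigines = c("yes" = 1, "no" = 0),
  sunburn    = c("yes" = 1, "no" = 0)
)

#' Read a phenotype/questionnaire table
#'
#' TSV with columns `sample_id, sex, status` and the six trait columns
#' `eye, hair, skin, naevi, lentigines, sunburn`. Trait cells may be coded
#' categories (e.g. `blue`, `brown` for eye; `fair`/`dark` for skin; `yes`/`no`
#' for lentigines and sunburn; `>=50`/`<50` for naevi), already-numeric `0`/`1`,
#' or `NA`. Categories are mapped to the fixed risk coding (1 = light
#' pigmentation / poor sun tolerance). Rows with missing sex or status are
#' rejected with an error naming the samples.
#'
#' @param path File path.
#' @return A [sample_records()] tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, colClasses = "character", na.strings = c("NA", ""))
  need <- c("sample_id", "sex", "status", TRAIT_NAMES)
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  bad <- is.na(x$sex) | !x$sex %in% c("F", "M") |
    is.na(x$status) | !x$status %in% c("case", "control")
  if (any(bad)) {
    stop("rejected record(s) with missing/invalid sex or status: ",
         paste(x$sample_id[bad], collapse = ", "))
  }
  decode <- function(cell, trait) {
    map <- TRAIT_CODING[[trait]]
    out <- rep(NA_integer_, length(cell))
    low <- tolower(cell)
    known <- !is.na(cell) & (low %in% names(map) | cell %in% c("0", "1"))
    unknown <- !is.na(cell) & !known
    if (any(unknown)) {
      stop(sprintf("unknown %s category '%s' for sample %s",
                   trait, cell[which(unknown)[1]], x$sample_id[which(unknown)[1]]))
    }
    numeric_in <- !is.na(cell) & cell %in% c("0", "1")
    out[numeric_in] <- as.integer(cell[numeric_in])
    cat_in <- !is.na(cell) & low %in% names(map)
    out[cat_in] <- as.integer(map[low[cat_in]])
    out
  }
  sample_records(
    sample_id = x$sample_id, sex = x$sex, status = x$status,
    eye = decode(x$eye, "eye"), hair = decode(x$hair, "hair"),
    skin = decode(x$skin, "skin"), naevi = decode(x$naevi, "naevi"),
    lentigines = decode(x$lentigines, "lentigines"),
    sunburn = decode(x$sunburn, "sunburn")
  )
}

#' Write a result table as TSV
#'
#' Deterministic writer for the pipeline's result tables: one header row,
#' floating-point values rendered with 8 significant digits, rows in the order
#' given (callers pass panel order, then stratum, then trait). Re-running on
#' identical input produces a byte-identical file.
#'
#' @param records A data frame sharing one schema (any of the result types).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  for (j in seq_along(records)) {
    if (is.double(records[[j]])) {
      records[[j]] <- formatC(records[[j]], digits = 8, format = "g")
      records[[j]][records[[j]] %in% c("NA", " NA")] <- NA
    }
  }
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Write a genotype matrix in the canonical TSV dialect
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(gm, path) {
  df <- data.frame(sample_id = gm$samples, gm$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
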