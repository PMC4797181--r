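#' @importFrom rlang .data
#' @importFrom stats pchisq qnorm rbinom runif setNames plogis complete.cases
NULL

VALID_CHROMS <- c(as.character(1:22), "X")
TRAIT_NAMES <- c("eye", "hair", "skin", "naevi", "lentigines", "sunburn")
OUTCOME_NAMES <- c(TRAIT_NAMES, "melanoma")

#' Construct a variant annotation table
#'
#' Validates and normalises a per-SNP annotation table. Each variant carries an
#' rsID, a chromosome label (autosomes 1-22 or X), a 1-based position, a gene
#' label and its minor/major alleles as reported by the genotyping panel (no
#' strand flipping is attempted).
#'
#' @param rsid Character vector of unique SNP identifiers.
#' @param chrom Chromosome labels in `1..22` or `"X"`.
#' @param pos 1-based integer positions (non-negative).
#' @param gene Gene (region) labels.
#' @param minor_allele,major_allele Single-base allele codes; must differ
#'   within each variant.
#'
#' @return A tibble with one row per variant and columns
#'   `rsid, chrom, pos, gene, minor_allele, major_allele`.
#' @export
variant_info <- function(rsid, chrom, pos, gene, minor_allele, major_allele) {
  chrom <- as.character(chrom)
  if (anyDuplicated(rsid)) {
    stop("duplicated rsID(s): ",
         paste(unique(rsid[duplicated(rsid)]), collapse = ", "))
  }
  bad <- !chrom %in% VALID_CHROMS
  if (any(bad)) {
    stop("invalid chromosome label(s): ", paste(unique(chrom[bad]), collapse = ", "))
  }
  if (any(pos < 0)) stop("positions must be non-negative")
  same <- toupper(minor_allele) == toupper(major_allele)
  if (any(same)) {
    stop("minor and major allele identical for: ",
         paste(rsid[same], collapse = ", "))
  }
  tibble::tibble(
    rsid = as.character(rsid), chrom = chrom, pos = as.integer(pos),
    gene = as.character(gene),
    minor_allele = toupper(minor_allele), major_allele = toupper(major_allele)
  )
}

#' Construct a genotype matrix
#'
#' A genotype matrix holds per-sample, per-variant minor-allele dosages
#' (0, 1, 2 copies of the declared minor allele, or `NA` for a failed call)
#' together with the variant annotation. Dosage orientation is whatever the
#' source declared; [orient_minor_allele()] re-orients to the sample minor
#' allele.
#'
#' @param dosage Integer matrix, samples in rows, variants in columns; values
#'   in `{0, 1, 2, NA}`. Row names are sample identifiers.
#' @param variants Variant annotation as produced by [variant_info()]; row
#'   order must match the dosage columns.
#' @param samples Optional character vector of sample identifiers (defaults to
#'   `rownames(dosage)`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (matrix), `variants` (tibble), `samples` (character).
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) stop("sample identifiers required")
  if (length(samples) != nrow(dosage)) {
    stop("sample list length does not match dosage rows")
  }
  if (nrow(variants) != ncol(dosage)) {
    stop("variant table rows (", nrow(variants),
         ") do not match dosage columns (", ncol(dosage), ")")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && (any(vals < 0L) || any(vals > 2L))) {
    stop("dosage values outside {0, 1, 2, NA}")
  }
  rownames(dosage) <- samples
  colnames(dosage) <- variants$rsid
  structure(
    list(dosage = dosage, variants = variants, samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants (%.2f%% missing calls)\n",
    length(x$samples), nrow(x$variants), 100 * miss
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by variant
#'
#' @param gm A [genotype_matrix()].
#' @param keep Logical or integer index over variants.
#' @return A `genotype_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(gm, keep) {
  genotype_matrix(gm$dosage[, keep, drop = FALSE],
                  gm$variants[keep, , drop = FALSE],
                  samples = gm$samples)
}

#' Construct phenotype/sample records
#'
#' One row per sample: sex (`"F"`/`"M"`), melanoma case-control status
#' (`"case"`/`"control"`) and six binary pigmentation / sun-sensitivity traits
#' coded on a fixed risk scale: 1 always means the light-pigmentation or
#' poor-sun-tolerance phenotype (blue/green eyes, blond/red hair, fair skin,
#' >= 50 naevi, lentigines present, childhood sunburns present) and 0 the
#' dark/tolerant phenotype, so that OR > 1 uniformly reads as the risk
#' direction. Sex and status may not be missing; traits may be `NA`.
#'
#' @param sample_id Unique sample identifiers.
#' @param sex `"F"` or `"M"`; never missing.
#' @param status `"case"` or `"control"`; never missing.
#' @param eye,hair,skin,naevi,lentigines,sunburn Trait codes in `{0, 1, NA}`.
#'
#' @return A tibble with class column types enforced.
#' @export
sample_records <- function(sample_id, sex, status, eye = NA, hair = NA,
                           skin = NA, naevi = NA, lentigines = NA,
                           sunburn = NA) {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicated sample_id")
  sex <- as.character(sex); status <- as.character(status)
  if (anyNA(sex) || !all(sex %in% c("F", "M"))) {
    bad <- sample_id[is.na(sex) | !sex %in% c("F", "M")]
    stop("missing/invalid sex for sample(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(status) || !all(status %in% c("case", "control"))) {
    bad <- sample_id[is.na(status) | !status %in% c("case", "control")]
    stop("missing/invalid status for sample(s): ", paste(bad, collapse = ", "))
  }
  chk <- function(x, nm) {
    x <- as.integer(x)
    if (any(!is.na(x) & !x %in% 0:1)) stop("trait '", nm, "' outside {0, 1, NA}")
    rep_len(x, n)
  }
  tibble::tibble(
    sample_id = as.character(sample_id), sex = sex, status = status,
    eye = chk(eye, "eye"), hair = chk(hair, "hair"), skin = chk(skin, "skin"),
    naevi = chk(naevi, "naevi"), lentigines = chk(lentigines, "lentigines"),
    sunburn = chk(sunburn, "sunburn")
  )
}

# Binary outcome vector (0/1/NA) for one outcome name, aligned to sample ids.
outcome_vector <- function(samples, outcome) {
  outcome <- match.arg(outcome, OUTCOME_NAMES)
  if (outcome == "melanoma") {
    as.integer(samples$status == "case")
  } else {
    samples[[outcome]]
  }
}
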