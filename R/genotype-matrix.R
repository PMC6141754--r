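#' Construct a genotype score matrix
#'
#' Container for array-genotyped biallelic SNP scores on the -1/0/1 scale
#' (-1 and 1 the two homozygotes, 0 the heterozygote), with `NA` marking
#' missing calls, plus optional per-genotype population labels.
#'
#' @param scores Numeric matrix, genotypes in rows and SNPs in columns.
#'   Row and column names are used as genotype and SNP ids; defaults are
#'   generated when absent. Non-missing entries must lie in \{-1, 0, 1\}.
#' @param population Optional character/factor vector of per-genotype
#'   population labels, recycled names permitted.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `scores` (the matrix) and `population` (factor or `NULL`).
#' @examples
#' m <- matrix(c(-1, 0, 1, 0, NA, 1), nrow = 3,
#'             dimnames = list(paste0("G", 1:3), c("S1", "S2")))
#' gm <- genotype_matrix(m)
#' dim(gm)
#' @export
genotype_matrix <- function(scores, population = NULL) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  ok <- is.na(scores) | scores %in% c(-1, 0, 1)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("genotype scores must be -1, 0, 1 or NA; offending value ",
         scores[bad], " at entry ", bad)
  }
  if (is.null(rownames(scores)))
    rownames(scores) <- sprintf("G%03d", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    colnames(scores) <- sprintf("SNP%05d", seq_len(ncol(scores)))
  if (anyDuplicated(rownames(scores)))
    stop("duplicate genotype ids")
  if (anyDuplicated(colnames(scores)))
    stop("duplicate SNP ids")
  if (!is.null(population)) {
    if (length(population) != nrow(scores))
      stop("population labels must match genotype count")
    population <- factor(population)
  }
  structure(list(scores = scores, population = population),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$scores)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$scores), "genotypes x",
      ncol(x$scores), "SNPs\n")
  miss <- mean(is.na(x$scores))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  if (!is.null(x$population))
    cat("  populations:",
        paste(sprintf("%s (%d)", levels(x$population),
                      tabulate(x$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Genotype ids of a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Character vector of genotype ids.
#' @export
genotype_ids <- function(gm) rownames(gm$scores)

#' SNP ids of a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Character vector of SNP ids.
#' @export
snp_ids <- function(gm) colnames(gm$scores)

#' Subset a genotype matrix
#' @param x A `genotype_matrix`.
#' @param i Genotype (row) index.
#' @param j SNP (column) index.
#' @param ... Ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$scores))
  if (missing(j)) j <- seq_len(ncol(x$scores))
  genotype_matrix(x$scores[i, j, drop = FALSE],
                  population = if (!is.null(x$population)) x$population[i])
}

#' Construct a genetic map table
#'
#' @param snp_id Character vector of SNP ids.
#' @param linkage_group Integer linkage-group id per SNP (`NA` for
#'   unmapped SNPs).
#' @param cM Map position in centimorgans (`NA` for unmapped SNPs).
#' @param isotig Optional isotig (EST contig) id per SNP.
#' @param bp Optional within-isotig base-pair position.
#' @return A `data.frame` of class `genetic_map` with columns `snp_id`,
#'   `linkage_group`, `cM`, `isotig`, `bp` and logical `mapped`. A SNP is
#'   mapped iff both linkage group and cM position are present.
#' @export
genetic_map <- function(snp_id, linkage_group, cM, isotig = NA, bp = NA) {
  if (anyDuplicated(snp_id)) stop("duplicate SNP ids in map")
  mapped <- !is.na(linkage_group) & !is.na(cM)
  if (any(cM[mapped] < 0)) stop("cM positions must be non-negative")
  out <- data.frame(snp_id = as.character(snp_id),
                    linkage_group = as.integer(linkage_group),
                    cM = as.numeric(cM),
                    isotig = as.character(isotig),
                    bp = as.numeric(bp),
                    mapped = mapped,
                    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Read genotype scores from TSV or VCF
#'
#' TSV layout: first column genotype id, remaining columns one per SNP with
#' values -1/0/1 or NA. VCF: diploid GT fields are recoded
#' 0/0 -> -1, 0/1 or 1/0 -> 0, 1/1 -> 1, missing -> NA; multi-allelic
#' records and non-diploid calls are rejected.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @param population Optional per-genotype population labels.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           population = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = 1)
    m <- as.matrix(tab)
    bad <- which(!(is.na(m) | m %in% c(-1, 0, 1)))
    if (length(bad)) {
      row <- ((bad[1] - 1) %% nrow(m)) + 1
      stop("malformed genotype score in data row ", row, " of ", path)
    }
    return(genotype_matrix(m, population = population))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop("multi-allelic VCF records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  score_of <- c("0/0" = -1, "0/1" = 0, "1/0" = 0, "1/1" = 1)
  known <- is.na(gt) | gt %in% c(names(score_of), "./.", ".")
  if (!all(known)) {
    v1 <- gt[which(!known)[1]]
    if (nchar(gsub("[^/]", "", v1)) != 1)
      stop("non-diploid GT call '", v1, "' in ", path)
    stop("unsupported GT call '", v1, "' in ", path)
  }
  sc <- matrix(unname(score_of[gt]), nrow = nrow(gt),
               dimnames = dimnames(gt))
  m <- t(sc)  # genotypes x SNPs
  snp_id <- rownames(gt)
  if (is.null(snp_id) || anyDuplicated(snp_id))
    snp_id <- sprintf("SNP%05d", seq_len(ncol(m)))
  colnames(m) <- snp_id
  genotype_matrix(m, population = population)
}

#' Write genotype scores as TSV
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotypes_tsv <- function(gm, path) {
  df <- data.frame(genotype_id = genotype_ids(gm), gm$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotype scores as VCF
#'
#' Emits a minimal VCF v4.2 with one contig per linkage group and
#' position `round(cM * 1e4)`; unmapped SNPs go on contig `LG0` with
#' ordinal positions. Scores are recoded back to diploid GT calls.
#'
#' @param gm A `genotype_matrix`.
#' @param map A [genetic_map()] covering the SNPs (optional).
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(gm, path, map = NULL) {
  snps <- snp_ids(gm)
  if (!is.null(map)) {
    m <- map[match(snps, map$snp_id), ]
    chrom <- ifelse(m$mapped, paste0("LG", m$linkage_group), "LG0")
    pos <- ifelse(m$mapped, round(m$cM * 1e4), seq_along(snps))
  } else {
    chrom <- rep("LG0", length(snps))
    pos <- seq_along(snps)
  }
  gt_of <- function(s) {
    out <- rep("./.", length(s))
    out[!is.na(s) & s == -1] <- "0/0"
    out[!is.na(s) & s == 0] <- "0/1"
    out[!is.na(s) & s == 1] <- "1/1"
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", unique(chrom), ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", genotype_ids(gm)),
                     collapse = "\t")), con)
  for (j in seq_along(snps)) {
    writeLines(paste(c(chrom[j], pos[j], snps[j], "A", "G", ".", "PASS",
                       ".", "GT", gt_of(gm$scores[, j])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a genetic map from TSV
#'
#' Expects columns `snp_id`, `linkage_group`, `cM`, and optionally
#' `isotig`, `bp`.
#' @param path File path.
#' @return A [genetic_map()].
#' @export
read_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  genetic_map(tab$snp_id, tab$linkage_group, tab$cM,
              isotig = if ("isotig" %in% names(tab)) tab$isotig else NA,
              bp = if ("bp" %in% names(tab)) tab$bp else NA)
}

#' Write a genetic map as TSV
#' @param map A [genetic_map()].
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[c("snp_id", "linkage_group",
                                          "cM", "isotig", "bp")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
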