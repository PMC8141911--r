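#' Write a genotype matrix to VCF 4.2
#'
#' Plain-text VCF with `GT` and `DP` per-genotype fields; the locus id
#' becomes the CHROM column.  Missing genotypes are written as `./.` with
#' their recorded depth.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path (uncompressed `.vcf`).
#' @param ref,alt reference and alternate alleles written for every site.
#' @return `gm`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path, ref = "A", alt = "T") {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=refugia",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$ind), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  n_site <- n_sites(gm)
  if (n_site > 0) {
    body <- vapply(seq_len(n_site), function(s) {
      g <- gm$gt[, s]
      d <- gm$depth[, s]
      cell <- ifelse(is.na(g), "./.", gt_code[g + 1L])
      cell <- paste(cell, d, sep = ":")
      paste(c(gm$sites$locus[s], gm$sites$pos[s], ".", ref, alt, ".",
              "PASS", ".", "GT:DP", cell), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(gm)
}

#' Read a biallelic SNP VCF into a genotype matrix
#'
#' Uses \pkg{vcfR} for parsing; keeps biallelic sites only.  Genotypes are
#' recoded as alternate-allele counts; `DP` is taken from the genotype field
#' when present (0 otherwise).
#'
#' @param path VCF file path.
#' @param popmap optional data frame (`ind`, `pop`) or path to a plain-text
#'   population map; individuals default to a single population `"pop1"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, popmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  biallelic <- vcfR::is.biallelic(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                     error = function(e) NULL)
  gt_raw <- gt_raw[biallelic, , drop = FALSE]
  if (!is.null(dp_raw)) dp_raw <- dp_raw[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    out[x %in% "0"] <- 0L   # haploid calls
    out[x %in% "1"] <- 1L
    out
  }
  gt <- t(matrix(code(as.vector(gt_raw)), nrow = nrow(gt_raw)))
  dp <- if (is.null(dp_raw)) matrix(0L, nrow(gt), ncol(gt))
        else t(matrix(as.integer(dp_raw), nrow = nrow(dp_raw)))
  dp[is.na(dp)] <- 0L
  ind <- colnames(gt_raw)
  pop <- rep("pop1", length(ind))
  if (!is.null(popmap)) {
    pm <- if (is.character(popmap)) read_popmap(popmap) else
      tibble::as_tibble(popmap)
    pop <- pm$pop[match(ind, pm$ind)]
    if (anyNA(pop))
      stop("population map does not cover all VCF individuals", call. = FALSE)
  }
  genotype_matrix(gt, pop = pop, depth = dp,
                  sites = tibble::tibble(locus = fix[, "CHROM"],
                                         pos = as.integer(fix[, "POS"])),
                  ind = ind)
}

#' Read/write a plain-text population map
#'
#' One line per individual: `individual<TAB>population`.
#'
#' @param gm a `genotype_matrix` (for writing).
#' @param path file path.
#' @return A tibble with columns `ind` and `pop`.
#' @export
read_popmap <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("ind", "pop"),
                   colClasses = "character")
  tibble::as_tibble(df)
}

#' @rdname read_popmap
#' @export
write_popmap <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  write.table(data.frame(gm$ind, gm$pop), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(gm)
}
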