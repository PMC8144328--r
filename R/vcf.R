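#' Ingest genotype dosages from a VCF file
#'
#' Converts a VCF into the genotype tibble used by [compute_score()]. The
#' `DS` FORMAT field (imputed dosage of the ALT allele) is used when
#' present; otherwise hard genotypes are counted from `GT`. The ALT
#' allele is taken as the dosage allele; orientation to the
#' BMI-increasing allele remains the caller's responsibility (supply
#' `allele_info` to [compute_score()] to have mismatches flagged).
#'
#' Requires the `vcfR` package.
#'
#' @param path VCF file (plain or gzipped).
#' @return A tibble with `id` (sample names) and one dosage column per
#'   variant, named by the VCF ID field (or `chrom_pos` when ID is
#'   missing), with attribute `allele_info` giving the ALT allele per SNP.
#' @export
genotypes_from_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("genotypes_from_vcf() requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, "_", fix$POS), fix$ID)
  fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(fmt) || all(is.na(fmt))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- apply(gt, 2, function(col) {
      vapply(strsplit(gsub("\\|", "/", col), "/", fixed = FALSE), function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    })
    if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(v@gt) , byrow = FALSE)
  }
  out <- tibble::as_tibble(t(fmt), .name_repair = "minimal")
  names(out) <- snp_id
  out <- dplyr::mutate(out, id = colnames(fmt), .before = 1)
  attr(out, "allele_info") <- tibble::tibble(snp_id = snp_id,
                                             effect_allele = fix$ALT)
  out
}
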