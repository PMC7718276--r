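# VCF v4.2 input/output for variant records. Reading goes through vcfR;
# writing emits plain text so call sets stay diff- and version-control
# friendly. Per-sample FORMAT fields are DP and AF; the first sample column
# is the tumour, the second the normal.

#' Write variant records as VCF v4.2
#'
#' Emits a two-sample (tumour, normal) VCF with per-sample `DP` and `AF`
#' FORMAT fields and `GENE`/`EFFECT`/`CALLER` INFO keys.
#'
#' @param variants variant data frame (see [somatic_filter()] for columns).
#' @param path output file path.
#' @param tumour_id,normal_id sample column names.
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(variants, path, tumour_id = "TUMOUR",
                              normal_id = "NORMAL") {
  validate_variants(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mraxis",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Annotated gene">',
    '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Predicted effect">',
    '##INFO=<ID=CALLER,Number=1,Type=String,Description="Originating caller">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Variant allele frequency">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", tumour_id, normal_id, sep = "\t"))
  body <- character(0)
  if (nrow(variants)) {
    info <- sprintf("GENE=%s;EFFECT=%s;CALLER=%s",
                    variants$gene %||% ".", variants$effect %||% ".",
                    variants$caller %||% ".")
    body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, ".", "PASS", info, "DP:AF",
                  sprintf("%d:%.4f", variants$tumour_depth, variants$tumour_vaf),
                  sprintf("%d:%.4f", variants$normal_depth, variants$normal_vaf),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant data frame
#'
#' Parses a (plain or gzipped) VCF with vcfR. Per-sample `AF` is taken from
#' the FORMAT field when present; otherwise it is derived from `AD`
#' (alt reads / total); records offering neither raise an error.
#'
#' @param path VCF file path.
#' @return variant data frame with the columns used throughout the variant
#'   filtering functions.
#' @export
read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), tumour_depth = integer(),
                      tumour_vaf = numeric(), normal_depth = integer(),
                      normal_vaf = numeric(), effect = character(),
                      gene = character(), caller = character(),
                      stringsAsFactors = FALSE)
  if (nrow(vcf@fix) == 0L) return(empty)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  fmt <- vcfR::vcf_field_names(vcf, tag = "FORMAT")
  if ("AF" %in% fmt$ID) {
    af <- vcfR::extract.gt(vcf, "AF", as.numeric = TRUE)
  } else if ("AD" %in% fmt$ID) {
    ad <- vcfR::extract.gt(vcf, "AD")
    alt_reads <- apply(ad, 2, function(x)
      vapply(strsplit(x, ","), function(p) as.numeric(p[2]), numeric(1)))
    af <- alt_reads / dp
  } else {
    stop("VCF provides neither AF nor AD; cannot derive allele frequencies",
         call. = FALSE)
  }
  if (ncol(dp) < 2L)
    stop("expected two sample columns (tumour, normal)", call. = FALSE)
  info1 <- function(key) {
    x <- vcfR::extract.info(vcf, key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT,
             tumour_depth = as.integer(dp[, 1]), tumour_vaf = as.numeric(af[, 1]),
             normal_depth = as.integer(dp[, 2]), normal_vaf = as.numeric(af[, 2]),
             effect = info1("EFFECT"), gene = info1("GENE"),
             caller = info1("CALLER"), stringsAsFactors = FALSE)
}
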