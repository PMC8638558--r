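#' Read population genotypes into per-subpopulation allele counts
#'
#' Parses the GT field of a VCF together with a two-column popmap TSV
#' (`sample`, `subpop`). Only biallelic SNV sites are kept; indel and
#' multiallelic sites are skipped (the skip count is attached as attribute
#' `skipped` and reported via a message). Missing calls (`./.`) contribute
#' no allele counts. Diploid genotypes contribute two counts each.
#'
#' @param vcf_path Path to a plain-text VCF (v4.x) with GT fields.
#' @param popmap_path Path to the popmap TSV.
#' @return A tibble with columns `snv_id` (`CHROM:POS`), `chrom`, `pos`
#'   (1-based, as in the VCF), `subpop`, `allele`, `count`.
#' @export
read_vcf_population <- function(vcf_path, popmap_path) {
  popmap <- readr::read_tsv(popmap_path, comment = "#", progress = FALSE,
                            show_col_types = FALSE,
                            col_types = readr::cols(
                              sample = readr::col_character(),
                              subpop = readr::col_character()))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  samples <- colnames(vcf@gt)[-1]
  unknown <- setdiff(samples, popmap$sample)
  if (length(unknown) > 0) {
    abort(sprintf("%s: sample(s) missing from popmap: %s", vcf_path,
                  paste(unknown, collapse = ", ")))
  }
  is_snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$REF != "." & fix$ALT != "."
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    inform(sprintf("read_vcf_population: skipped %d non-biallelic-SNV site(s)",
                   n_skipped))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snv, , drop = FALSE]
  fix <- fix[is_snv, , drop = FALSE]
  if (nrow(fix) == 0) {
    out <- tibble::tibble(snv_id = character(), chrom = character(),
                          pos = integer(), subpop = character(),
                          allele = character(), count = integer())
    attr(out, "skipped") <- n_skipped
    return(out)
  }
  long <- tibble::tibble(
    site_idx = rep(seq_len(nrow(gt)), times = ncol(gt)),
    sample = rep(colnames(gt), each = nrow(gt)),
    gt = as.vector(gt)) |>
    dplyr::left_join(popmap, by = "sample")
  # count ref/alt alleles from diploid GT strings; "." calls dropped
  alleles <- stringr::str_split(gsub("|", "/", long$gt, fixed = TRUE), "/")
  long$n_ref <- purrr::map_int(alleles, ~ sum(.x %in% "0"))
  long$n_alt <- purrr::map_int(alleles, ~ sum(.x %in% "1"))
  counts <- long |>
    dplyr::summarise(ref = sum(.data$n_ref), alt = sum(.data$n_alt),
                     .by = c("site_idx", "subpop")) |>
    dplyr::mutate(chrom = fix$CHROM[.data$site_idx],
                  pos = as.integer(fix$POS[.data$site_idx]),
                  ref_allele = as_rna(fix$REF[.data$site_idx]),
                  alt_allele = as_rna(fix$ALT[.data$site_idx]))
  out <- dplyr::bind_rows(
    dplyr::transmute(counts, chrom = .data$chrom, pos = .data$pos,
                     subpop = .data$subpop, allele = .data$ref_allele,
                     count = .data$ref),
    dplyr::transmute(counts, chrom = .data$chrom, pos = .data$pos,
                     subpop = .data$subpop, allele = .data$alt_allele,
                     count = .data$alt)) |>
    dplyr::mutate(snv_id = paste0(.data$chrom, ":", .data$pos)) |>
    dplyr::select("snv_id", "chrom", "pos", "subpop", "allele", "count") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$subpop, .data$allele)
  attr(out, "skipped") <- n_skipped
  out
}

#' Write a minimal VCF with genotype calls
#'
#' Emits a plain-text VCF v4.2 with GT-only genotypes, suitable for
#' round-tripping through [read_vcf_population()].
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param genotypes Integer matrix of alt-allele dosages (0/1/2), sites in
#'   rows, samples in columns (column names = sample ids); `NA` = missing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(sites, genotypes, path) {
  stopifnot(nrow(sites) == nrow(genotypes))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L],
                   nrow = nrow(genotypes))
  gt_str[is.na(gt_str)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=ribostruct",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(genotypes)),
                    collapse = "\t"))
  rows <- paste(sites$chrom, sites$pos, ".",
                gsub("U", "T", sites$ref, fixed = TRUE),
                gsub("U", "T", sites$alt, fixed = TRUE),
                ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}
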