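# Plain-text interchange: VCF / CSV genotypes, TSV design and maps,
# JSON/YAML metadata.

#' Write a genotype table as VCF
#'
#' One record per marker with a `GT` field per individual (0/0, 0/1, 1/1,
#' ./.) and contig headers from the chromosome table. Requires the vcfR
#' package.
#'
#' @param geno A `genotype_table`.
#' @param chrom_spec Chromosome tibble (`chrom`, `length_bp`).
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, chrom_spec, path) {
  rlang::check_installed("vcfR")
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%d>", chrom_spec$chrom,
                    as.integer(chrom_spec$length_bp)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", ncol(geno$calls), nrow(geno$calls),
               dimnames = list(NULL, rownames(geno$calls)))
  calls_t <- t(geno$calls)
  ok <- !is.na(calls_t)
  gt[ok] <- gt_code[as.character(calls_t[ok])]
  fix <- cbind(CHROM = geno$markers$chrom,
               POS = format(geno$markers$pos + 1, scientific = FALSE,
                            trim = TRUE),
               ID = geno$markers$marker, REF = "A", ALT = "T",
               QUAL = ".", FILTER = "PASS", INFO = ".")
  vcf <- methods::new("vcfR", meta = meta, fix = fix,
                      gt = cbind(FORMAT = "GT", gt))
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read a VCF into a genotype table
#'
#' @param path VCF path.
#' @return A `genotype_table` in allele coding (quality 1, population
#'   `"unknown"` unless encoded as `pop_id` in the sample names as
#'   `POP_RIL`).
#' @export
read_genotypes_vcf <- function(path) {
  rlang::check_installed("vcfR")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf)
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  calls <- t(apply(gt, 2, code))
  colnames(calls) <- rownames(gt)
  ids <- colnames(gt)
  pop <- sub("_R[0-9]+$", "", ids)
  markers <- tibble::tibble(marker = rownames(gt),
                            chrom = vcfR::getCHROM(vcf),
                            pos = vcfR::getPOS(vcf) - 1,
                            quality = 1)
  new_genotype_table(calls, tibble::tibble(id = ids, pop_id = pop), markers)
}

#' Write a genotype table as a CSV matrix
#'
#' Individuals x markers, first column `id`, `NA` for missing calls.
#'
#' @param geno A `genotype_table`.
#' @param path Output path.
#' @export
write_genotypes_csv <- function(geno, path) {
  df <- tibble::as_tibble(geno$calls, rownames = "id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Write / read a crossing design as TSV
#'
#' @param design Crossing design tibble.
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write the simulation ground truth as YAML or JSON
#'
#' @param truth A `recomb_truth`.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @export
write_truth <- function(truth, path) {
  x <- list(tau2_g = truth$tau2_g, tau2_s = truth$tau2_s,
            window_bp = truth$window_bp,
            baseline = as.list(truth$baseline),
            gre = as.list(truth$gre), sre = as.list(truth$sre))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write window rates as BED-like TSV
#'
#' Columns `chrom`, `start`, `end`, `pop_id`, `rate`.
#'
#' @param wr A `window_rates` tibble.
#' @param path Output path.
#' @export
write_window_rates_tsv <- function(wr, path) {
  readr::write_tsv(dplyr::select(wr, "chrom", "start", "end", "pop_id",
                                 "rate"), path)
  invisible(path)
}

#' Write a linkage map as TSV
#'
#' Columns `chrom`, `bin`, `cM`, `anchor_bp`, `member_markers`
#' (comma-separated).
#'
#' @param linkmap Linkage map tibble.
#' @param path Output path.
#' @export
write_linkage_map_tsv <- function(linkmap, path) {
  out <- linkmap |>
    dplyr::mutate(member_markers = vapply(.data$markers, paste,
                                          character(1), collapse = ",")) |>
    dplyr::select("chrom", "bin", "cM", "anchor_bp", "member_markers")
  readr::write_tsv(out, path)
  invisible(path)
}
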