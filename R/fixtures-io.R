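dosage_to_gt <- function(X) {
  map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  out <- matrix("./.", nrow(X), ncol(X), dimnames = dimnames(X))
  ok <- !is.na(X)
  out[ok] <- map[as.character(X[ok])]
  out
}

gt_to_dosage <- function(gt) {
  map <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L,
           `0|0` = 0L, `0|1` = 1L, `1|0` = 1L, `1|1` = 2L)
  out <- matrix(map[gt], nrow(gt), ncol(gt), dimnames = dimnames(gt))
  out
}

#' Write a dosage matrix as a VCF v4.2 file
#'
#' @param G Dosage matrix (individuals x variants; `NA` = missing).
#' @param variants Tibble with `variant_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param path Output path; `.vcf.gz` compression is applied when the path
#'   ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(G, variants, path) {
  stopifnot(ncol(G) == nrow(variants))
  fix <- cbind(CHROM = as.character(variants$chrom),
               POS = as.character(variants$pos),
               ID = variants$variant_id, REF = variants$ref,
               ALT = variants$alt, QUAL = ".", FILTER = "PASS", INFO = ".")
  gt <- cbind(FORMAT = "GT", t(dosage_to_gt(G)))
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  ok <- tryCatch({
    vcfR::write.vcf(v, file = path)
    TRUE
  }, error = function(e) {
    abort(paste0("failed to write VCF at ", path, ": ", conditionMessage(e)))
  })
  invisible(path)
}

#' Read a VCF into a dosage matrix plus variant table
#'
#' @param path VCF (optionally gzipped) with GT genotypes.
#' @return List with `genotypes` (individuals x variants integer matrix) and
#'   `variants` (tibble: variant_id, chrom, pos, ref, alt).
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  G <- t(gt_to_dosage(gt))
  fix <- v@fix
  variants <- tibble::tibble(variant_id = fix[, "ID"],
                             chrom = fix[, "CHROM"],
                             pos = as.integer(fix[, "POS"]),
                             ref = fix[, "REF"], alt = fix[, "ALT"])
  colnames(G) <- variants$variant_id
  list(genotypes = G, variants = variants)
}

#' Write a simulated cohort to disk as analysis-ready study inputs
#'
#' Produces one VCF per center plus the truth VCF, a phenotype TSV, a
#' variant annotation TSV, a BED target-region table and a JSON record of
#' the true model. [read_cohort_fixture()] round-trips the matrices exactly.
#'
#' @param cohort An `rl_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rl_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(truth = file.path(dir, "truth.vcf.gz"),
             center1 = file.path(dir, "center1.vcf.gz"),
             center2 = file.path(dir, "center2.vcf.gz"),
             center3 = file.path(dir, "center3.vcf.gz"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             regions = file.path(dir, "targets.bed"),
             true_model = file.path(dir, "true_model.json"))
  write_genotype_vcf(cohort$genotypes, cohort$variants, paths[["truth"]])
  for (k in 1:3) {
    cs <- cohort$centers[[k]]
    vv <- cohort$variants
    vv$alt <- cs$alleles$alt[match(vv$variant_id, cs$alleles$variant_id)]
    write_genotype_vcf(cs$genotypes, vv, paths[[cs$center]])
  }
  readr::write_tsv(cohort$phenotypes, paths[["phenotypes"]])
  readr::write_tsv(
    dplyr::select(cohort$variants, "variant_id", "gene", "consequence"),
    paths[["annotations"]])
  bed <- purrr::map_dfr(cohort$config$loci, function(l) {
    tibble::tibble(chrom = l$chrom, start = l$start,
                   end = l$start + l$length_bp, name = l$gene)
  })
  readr::write_tsv(bed, paths[["regions"]], col_names = FALSE)
  jsonlite::write_json(
    list(effects = cohort$true_model$effects,
         variance_explained = cohort$true_model$variance_explained,
         monomorphic_sites = cohort$true_model$monomorphic_sites,
         artifact_sites = attr(cohort$centers, "artifact_sites")),
    paths[["true_model"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort fixture written by [write_cohort_fixture()]
#'
#' @param dir Directory containing the fixture files.
#' @return List with `genotypes`, `variants`, `centers`, `phenotypes`,
#'   `annotations`, `regions` and `true_model`.
#' @export
read_cohort_fixture <- function(dir) {
  truth <- read_genotype_vcf(file.path(dir, "truth.vcf.gz"))
  centers <- lapply(1:3, function(k) {
    r <- read_genotype_vcf(file.path(dir, paste0("center", k, ".vcf.gz")))
    structure(list(center = paste0("center", k), genotypes = r$genotypes,
                   alleles = r$variants[, c("variant_id", "ref", "alt")]),
              class = "rl_center_callset")
  })
  phen <- readr::read_tsv(file.path(dir, "phenotypes.tsv"),
                          show_col_types = FALSE)
  ann <- readr::read_tsv(file.path(dir, "annotations.tsv"),
                         show_col_types = FALSE)
  bed <- readr::read_tsv(file.path(dir, "targets.bed"), col_names =
                           c("chrom", "start", "end", "name"),
                         show_col_types = FALSE)
  tm <- jsonlite::read_json(file.path(dir, "true_model.json"),
                            simplifyVector = TRUE)
  list(genotypes = truth$genotypes, variants = truth$variants,
       centers = centers, phenotypes = phen, annotations = ann,
       regions = bed, true_model = tm)
}
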