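#' @name cohort-io
#' @title Read and write phenotype/covariate cohort tables
#'
#' @description Tab-delimited cohort tables use the columns `FID`, `IID`,
#' `region_birth`, `region_current`, `sex`, `age`, `PRS`, and one `pheno_*`
#' column per trait. Reading validates the required columns and reports parse
#' problems with their line numbers.
NULL

stop_on_parse_problems <- function(x, path) {
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    stop_invalid("parse error in ", path, " at line(s) ",
                 paste(utils::head(pr$row, 5), collapse = ", "),
                 ": ", pr$expected[1], " vs ", pr$actual[1])
  }
  x
}

#' @param cohort Cohort tibble (internal names `fid`, `iid`, `prs`, ...).
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble with internal column
#'   names; `write_cohort()` returns `path` invisibly.
#' @rdname cohort-io
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  ren <- c(FID = "fid", IID = "iid", PRS = "prs")
  for (new in names(ren)) {
    if (ren[[new]] %in% names(out)) {
      names(out)[names(out) == ren[[new]]] <- new
    }
  }
  out <- out[, !names(out) %in% c("g_true", "midparent_g", "sib"), drop = FALSE]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname cohort-io
#' @export
read_cohort <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stop_on_parse_problems(x, path)
  ren <- c(fid = "FID", iid = "IID", prs = "PRS")
  for (new in names(ren)) {
    if (ren[[new]] %in% names(x)) names(x)[names(x) == ren[[new]]] <- new
  }
  # fid is only needed by the sibling analyses; unrelated cohorts omit it
  req <- c("iid", "sex", "age")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop_invalid("cohort file ", path, " is missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  x
}

#' Read and write region layouts
#'
#' Layouts are stored as TSV with columns `region`, `ses`, `x`, `y`; the
#' rook-adjacency weight matrix is rebuilt from the grid coordinates on read.
#'
#' @param layout A `region_layout`.
#' @param path File path.
#' @return `read_region_layout()` returns a `region_layout`.
#' @export
write_region_layout <- function(layout, path) {
  readr::write_tsv(layout$regions, path)
  invisible(path)
}

#' @rdname write_region_layout
#' @export
read_region_layout <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stop_on_parse_problems(x, path)
  miss <- setdiff(c("region", "ses", "x", "y"), names(x))
  if (length(miss)) {
    stop_invalid("region layout ", path, " is missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  K <- nrow(x)
  W <- matrix(0, K, K)
  for (i in seq_len(K)) {
    nb <- which(abs(x$x - x$x[i]) + abs(x$y - x$y[i]) == 1)
    W[i, nb] <- 1
  }
  structure(list(regions = tibble::as_tibble(x), W = W),
            class = "region_layout")
}

#' Read and write association summary statistics
#'
#' Whitespace-delimited files with the header `SNP A1 A2 FRQ BETA SE Z N`
#' (the LDSC summary-statistic convention); files carrying only
#' `SNP A1 A2 N Z` are accepted on read.
#'
#' @param sumstats Summary-statistic tibble from [assoc_scan()].
#' @param path File path.
#' @return `read_sumstats()` returns a tibble with internal lowercase names
#'   and a `chisq` column.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$snp, A1 = sumstats$a1, A2 = sumstats$a2,
                    FRQ = sumstats$frq, BETA = sumstats$beta,
                    SE = sumstats$se, Z = sumstats$z, N = sumstats$n)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- readr::read_table(path, show_col_types = FALSE)
  stop_on_parse_problems(x, path)
  miss <- setdiff(c("SNP", "A1", "A2", "Z", "N"), names(x))
  if (length(miss)) {
    stop_invalid("sumstats file ", path, " is missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  tibble::tibble(
    snp = x$SNP, a1 = x$A1, a2 = x$A2,
    frq = if ("FRQ" %in% names(x)) x$FRQ else NA_real_,
    beta = if ("BETA" %in% names(x)) x$BETA else NA_real_,
    se = if ("SE" %in% names(x)) x$SE else NA_real_,
    z = x$Z, chisq = x$Z^2, n = x$N
  )
}

#' Read and write plain-text genotype matrices
#'
#' Dosages are stored as a TSV with an `IID` column followed by one 0/1/2
#' column per SNP; the SNP map is a companion TSV with columns `SNP`, `CHR`,
#' `BP`, `A1`, `A2`, `MAF`.
#'
#' @param geno Dosage matrix.
#' @param snps SNP map tibble.
#' @param path,map_path File paths.
#' @param iid Optional individual ids.
#' @return `read_genotype_matrix()` returns `list(geno, snps, iid)`.
#' @export
write_genotype_matrix <- function(geno, snps, path, map_path,
                                  iid = sprintf("I%06d", seq_len(nrow(geno)))) {
  d <- as.data.frame(geno)
  names(d) <- snps$snp
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(IID = iid), d), path)
  readr::write_tsv(
    tibble::tibble(SNP = snps$snp, CHR = snps$chr, BP = snps$bp,
                   A1 = snps$a1, A2 = snps$a2, MAF = snps$maf),
    map_path
  )
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path, map_path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stop_on_parse_problems(x, path)
  m <- readr::read_tsv(map_path, show_col_types = FALSE)
  stop_on_parse_problems(m, map_path)
  miss <- setdiff(c("SNP", "CHR", "BP", "A1", "A2", "MAF"), names(m))
  if (length(miss)) {
    stop_invalid("SNP map ", map_path, " is missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  iid <- x$IID
  geno <- as.matrix(x[, setdiff(names(x), "IID"), drop = FALSE])
  storage.mode(geno) <- "integer"
  snps <- tibble::tibble(snp = m$SNP, chr = m$CHR, bp = m$BP, a1 = m$A1,
                         a2 = m$A2, maf = m$MAF)
  if (!identical(colnames(geno), snps$snp)) {
    stop_invalid("genotype columns and SNP map ids disagree")
  }
  list(geno = unname(geno), snps = snps, iid = iid)
}

#' Read and write genotypes as VCF
#'
#' `write_genotype_vcf()` emits a minimal plain-text VCFv4.2 with GT-only
#' genotypes (one sample per individual). `read_genotype_vcf()` parses any
#' VCF via the vcfR package, converting GT to dosages of the ALT allele;
#' multiallelic records are skipped with a warning reporting the count.
#'
#' @inheritParams write_genotype_matrix
#' @param path File path.
#' @return `read_genotype_vcf()` returns `list(geno, snps, iid)`.
#' @export
write_genotype_vcf <- function(geno, snps, path,
                               iid = sprintf("I%06d", seq_len(nrow(geno)))) {
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", iid), collapse = "\t")), con)
  for (j in seq_len(ncol(geno))) {
    writeLines(paste(c(snps$chr[j], snps$bp[j], snps$snp[j], snps$a2[j],
                       snps$a1[j], ".", "PASS", ".", "GT",
                       gt_code[geno[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_genotype_vcf
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_invalid("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  multi <- grepl(",", fx[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
  fx <- fx[!multi, , drop = FALSE]
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dose[clean %in% c("0/0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1")] <- 2L
  geno <- t(dose)
  snps <- tibble::tibble(
    snp = fx[, "ID"], chr = fx[, "CHROM"],
    bp = as.integer(fx[, "POS"]), a1 = fx[, "ALT"], a2 = fx[, "REF"],
    maf = colMeans(geno, na.rm = TRUE) / 2
  )
  list(geno = unname(geno), snps = snps, iid = colnames(gt))
}

#' Read a YAML run configuration
#'
#' The run file carries a `seed`, an `out_dir`, exactly one of a `simulate`
#' block (any [sim_config()] field) or a `data` block (paths to user-supplied
#' cohort/genotype files), and an optional `analysis` block (`models`,
#' `conditions`, `n_boot`, `n_pcs`, `min_region_n`, `fdr_alpha`). Missing
#' required fields are reported by name.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with elements `seed`, `out_dir`,
#'   `config` (a `sim_config`, when simulating), `data`, `analysis`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (field in c("seed")) {
    if (is.null(raw[[field]])) {
      stop_invalid("run config is missing required field '", field, "'")
    }
  }
  has_sim <- !is.null(raw$simulate)
  has_data <- !is.null(raw$data)
  if (has_sim == has_data) {
    stop_invalid("run config must have exactly one of 'simulate' or 'data'")
  }
  analysis <- utils::modifyList(
    list(models = 1:5, conditions = c("none", "birth", "current", "both"),
         n_boot = 500L, n_pcs = 10L, min_region_n = 100L, fdr_alpha = 0.05),
    raw$analysis %||% list()
  )
  cfg <- NULL
  if (has_sim) {
    args <- raw$simulate
    args$seed <- raw$seed
    cfg <- do.call(sim_config, args)
  }
  structure(list(seed = as.integer(raw$seed), out_dir = raw$out_dir %||% ".",
                 config = cfg, data = raw$data, analysis = analysis),
            class = "run_config")
}
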