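# Genotype input, filtering and covariate standardization.

#' Construct a genotype matrix object
#'
#' Container for a samples x SNPs dosage matrix (counts of the alternate
#' allele, 0/1/2, `NA` for missing) together with per-SNP metadata.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param samples character vector of sample IDs (length `nrow(dosage)`).
#' @param snps data frame with one row per SNP and at least columns `id`,
#'   `qual` (variant quality), `ref`, `alt`, `biallelic` (logical). Columns
#'   `lg` (linkage group) and `cm` (map position in centimorgans) may be `NA`
#'   until a linkage map is attached with [annotate_map()].
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, samples, snps) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(dosage) != length(samples))
    stop("`samples` length does not match the number of dosage rows")
  if (ncol(dosage) != nrow(snps))
    stop("`snps` rows do not match the number of dosage columns")
  needed <- c("id", "qual", "ref", "alt", "biallelic")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols))
    stop("`snps` is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(snps$lg)) snps$lg <- NA_integer_
  if (is.null(snps$cm)) snps$cm <- NA_real_
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- samples
  colnames(dosage) <- snps$id
  structure(list(dosage = dosage, samples = as.character(samples),
                 snps = as.data.frame(snps)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  n_map <- sum(!is.na(x$snps$lg) & !is.na(x$snps$cm))
  cat(sprintf("  mapped SNPs: %d; biallelic: %d; missing dosages: %.2f%%\n",
              n_map, sum(x$snps$biallelic),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (logical, integer or character).
#' @param j SNP index (logical, integer or character against SNP ids).
#' @param ... unused.
#' @return A `genotype_matrix` restricted to the selected samples/SNPs.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$snps))
  if (is.character(j)) j <- match(j, x$snps$id)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  x$samples[i],
                  x$snps[j, , drop = FALSE])
}

# GT strings ("0/1", "1|1", "./.") -> alt-allele counts; anything involving an
# allele code other than 0/1 (multiallelic calls) or a missing allele is NA.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  conv <- vapply(u, function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(gsub("|", "/", s, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (length(al) != 2 || any(al == ".") || any(!al %in% c("0", "1")))
      return(NA_real_)
    sum(al == "1")
  }, numeric(1))
  out <- matrix(conv[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  out
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.x) with GT fields into a [genotype_matrix()]. Dosages are
#' alternate-allele counts; missing genotypes (`./.`) become `NA`.
#' Multiallelic records are retained but flagged `biallelic = FALSE` (their
#' genotypes involving allele codes above 1 are set missing); filtering is
#' deferred to [filter_snps()].
#'
#' @param path path to a VCF file.
#' @return A `genotype_matrix` with SNP metadata (`id`, `chrom`, `pos`,
#'   `qual`, `ref`, `alt`, `biallelic`); `lg`/`cm` are `NA` until
#'   [annotate_map()] is applied.
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path,
                                         "': ", conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- t(gt_to_dosage(gt))
  id <- fix$ID
  auto <- paste0(fix$CHROM, "_", fix$POS)
  id <- ifelse(is.na(id) | id == ".", auto, id)
  snps <- data.frame(
    id = id,
    chrom = fix$CHROM,
    pos = suppressWarnings(as.integer(fix$POS)),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    ref = fix$REF,
    alt = fix$ALT,
    biallelic = !is.na(fix$ALT) & fix$ALT != "." & !grepl(",", fix$ALT),
    lg = NA_integer_,
    cm = NA_real_,
    stringsAsFactors = FALSE)
  genotype_matrix(dosage, colnames(gt), snps)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Minimal VCF v4.2 emitter (GT field only), the inverse of [read_vcf()] for
#' biallelic data: a write/read round trip preserves dosages exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  s <- g$snps
  chrom <- if (!is.null(s$chrom)) s$chrom else {
    ifelse(is.na(s$lg), "0", as.character(s$lg))
  }
  pos <- if (!is.null(s$pos) && !anyNA(s$pos)) s$pos else seq_len(nrow(s))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(s), length(g$samples))
  d <- t(g$dosage)
  ok <- !is.na(d)
  gt[ok] <- code[as.character(d[ok])]
  body <- cbind(chrom, pos, s$id, s$ref, s$alt,
                ifelse(is.na(s$qual), ".", format(s$qual, trim = TRUE)),
                "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Attach linkage-map positions to SNPs
#'
#' @param g a [genotype_matrix()].
#' @param map data frame with columns `snp_id`, `lg`, `cm`.
#' @return `g` with `lg` and `cm` filled in for mapped SNPs; unmapped SNPs
#'   keep `NA` (they are excluded from GRMs but usable for karyotyping).
#' @export
annotate_map <- function(g, map) {
  stopifnot(all(c("snp_id", "lg", "cm") %in% names(map)))
  idx <- match(g$snps$id, map$snp_id)
  g$snps$lg <- as.integer(map$lg[idx])
  g$snps$cm <- as.numeric(map$cm[idx])
  n_un <- sum(is.na(idx))
  if (n_un > 0)
    message(n_un, " SNPs have no linkage-map position")
  g
}

#' Filter SNPs on quality, minor allele frequency and call rate
#'
#' Retains only biallelic SNPs with variant quality `>= min_qual`, minor
#' allele frequency `>= min_maf` (computed from called dosages only) and at
#' least `min_called` samples with data. Defaults follow the standard capture
#' pipeline thresholds (quality 20, MAF 0.1). SNPs monomorphic among called
#' samples are always dropped. Allele frequencies are meaningful per site, so
#' apply this within one site's samples.
#'
#' @param g a [genotype_matrix()].
#' @param min_qual minimum variant quality (default 20).
#' @param min_maf minimum minor allele frequency (default 0.1).
#' @param min_called minimum number of samples with a called genotype.
#' @return The filtered `genotype_matrix`.
#' @export
filter_snps <- function(g, min_qual = 20, min_maf = 0.1, min_called = 0) {
  n <- length(g$samples)
  if (ncol(g$dosage) == 0) stop("empty genotype matrix")
  if (min_called > n)
    stop("min_called (", min_called, ") exceeds the number of samples (",
         n, ")")
  called <- colSums(!is.na(g$dosage))
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- g$snps$biallelic &
    !is.na(g$snps$qual) & g$snps$qual >= min_qual &
    called >= pmax(min_called, 1) &
    !is.na(maf) & maf > 0 & maf >= min_maf
  if (!any(keep)) stop("no SNPs survive filters")
  g[, which(keep)]
}

#' Z-score standardization with zero-filled missing values
#'
#' Centers and scales to unit sample standard deviation (n - 1 denominator)
#' using the non-missing entries, then replaces missing entries with 0 (the
#' mean of the standardized values).
#'
#' @param x numeric vector, possibly with `NA`.
#' @param name label used in error messages.
#' @return Numeric vector of the same length; non-missing entries have mean 0
#'   and SD 1, missing entries are 0.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  ok <- !is.na(x)
  if (sum(ok) < 2)
    stop("cannot standardize '", name, "': fewer than 2 non-missing values")
  s <- sd(x[ok])
  if (!is.finite(s) || s == 0)
    stop("cannot standardize '", name, "': zero variance")
  z <- (x - mean(x[ok])) / s
  z[!ok] <- 0
  z
}

#' Define inversion regions
#'
#' @param name inversion names (e.g. `"LGC6.1"`).
#' @param lg integer linkage group of each region.
#' @param cm_start,cm_end map interval in centimorgans (`cm_start < cm_end`).
#' @return data frame of class `inversion_regions`.
#' @export
inversion_regions <- function(name, lg, cm_start, cm_end) {
  stopifnot(length(name) == length(lg),
            length(cm_start) == length(name),
            length(cm_end) == length(name))
  if (any(cm_start >= cm_end))
    stop("cm_start must be < cm_end for every region")
  structure(data.frame(name = as.character(name), lg = as.integer(lg),
                       cm_start = as.numeric(cm_start),
                       cm_end = as.numeric(cm_end),
                       stringsAsFactors = FALSE),
            class = c("inversion_regions", "data.frame"))
}

#' Read a linkage map (TSV: snp_id, lg, cm)
#' @param path file path.
#' @return data frame with columns `snp_id`, `lg`, `cm`.
#' @export
read_linkage_map <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "lg", "cm") %in% names(m)))
  m
}

#' Read inversion region definitions (TSV: name, lg, cm_start, cm_end)
#' @param path file path.
#' @return An [inversion_regions()] data frame.
#' @export
read_inversion_regions <- function(path) {
  r <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "lg", "cm_start", "cm_end") %in% names(r)))
  inversion_regions(r$name, r$lg, r$cm_start, r$cm_end)
}

#' Read a per-sample table
#'
#' Expects at least `id`, `site`, `path_pos_m`, `shore_height_m`, `sex`,
#' `habitat_label`; remaining numeric columns are treated as traits.
#'
#' @param path file path (TSV).
#' @return data frame.
#' @export
read_sample_table <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("id", "site", "path_pos_m", "shore_height_m", "sex",
              "habitat_label")
  missing_cols <- setdiff(needed, names(s))
  if (length(missing_cols))
    stop("sample table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(s$path_pos_m < 0, na.rm = TRUE))
    stop("path_pos_m must be non-negative")
  s
}

#' Read environmental survey points (TSV: path_pos_m, substrate, barnacles, fucus)
#' @param path file path.
#' @return data frame with binary indicator columns.
#' @export
read_env_points <- function(path) {
  e <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("path_pos_m", "substrate", "barnacles", "fucus") %in%
                  names(e)))
  for (v in c("substrate", "barnacles", "fucus"))
    if (!all(e[[v]] %in% c(0, 1)))
      stop("indicator '", v, "' must be coded 0/1")
  e
}
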