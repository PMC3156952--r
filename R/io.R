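#' Read genotype data and its sample manifest
#'
#' Reads either a VCF 4.x file (biallelic SNP records; ancestral allele taken
#' from the standard `AA` INFO tag, `.` meaning unknown) or the package's
#' tab-separated genotype table dialect, together with a manifest TSV
#' (columns `sample`, `population`, `group`, `lat`, `lon`).  Genotype
#' separators `/` and `|` are both accepted; the matrix is flagged phased
#' only when every call is `|`-separated.
#'
#' @param path Path to a `.vcf` or `.tsv`/`.txt` genotype file.
#' @param manifest_path Path to the manifest TSV.
#' @return A list with elements `matrix` (a [genotype_matrix()]) and
#'   `manifest` (a [sample_manifest()]).
#' @export
read_genotype_data <- function(path, manifest_path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- sample_manifest(read.delim(manifest_path,
                                         stringsAsFactors = FALSE))
  ext <- tolower(tools::file_ext(path))
  gm <- if (ext == "vcf") read_genotype_vcf(path) else read_genotype_tsv(path)
  missing_samples <- setdiff(sample_ids(gm), manifest$sample)
  if (length(missing_samples))
    stop("sample(s) in genotype file absent from manifest: ",
         paste(missing_samples, collapse = ", "))
  list(matrix = gm, manifest = manifest)
}

# Decode a matrix of GT tokens ("0/1", "1|1", "./.", ...) into alt-allele
# copy counts.  Tokens mentioning allele indices > 1 are left NA (the record
# is multi-allelic and only survives until the QC filter).  Returns list
# (codes, phased).
decode_gt <- function(gt, multiallelic) {
  tok <- gsub("|", "/", gt, fixed = TRUE)
  codes <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA)
  idx <- match(tok, names(known))
  bad <- is.na(idx) & !is.na(tok)
  if (any(bad)) {
    if (any(bad & !multiallelic)) {
      w <- which(bad & !multiallelic, arr.ind = TRUE)[1, ]
      stop(sprintf("malformed genotype token '%s' at record %d, sample '%s'",
                   gt[w[1], w[2]], w[1], colnames(gt)[w[2]]))
    }
    # multi-allelic records: any token with allele index > 1 -> NA
    ok3 <- grepl("^[0-9.]+/[0-9.]+$", tok[bad])
    if (!all(ok3)) {
      w <- which(bad, arr.ind = TRUE)[which(!ok3)[1], ]
      stop(sprintf("malformed genotype token '%s' at record %d, sample '%s'",
                   gt[w[1], w[2]], w[1], colnames(gt)[w[2]]))
    }
  }
  codes[] <- unname(known[idx])
  phased <- all(grepl("|", gt[!is.na(gt)], fixed = TRUE)) &&
    any(!is.na(gt))
  list(codes = codes, phased = phased)
}

read_genotype_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  positions <- BiocGenerics::start(rr)
  region <- as.character(GenomeInfoDb::seqnames(rr))
  region <- if (length(region)) region[1] else "region1"
  sl <- GenomeInfoDb::seqlengths(rr)
  region_length <- if (length(sl) && !is.na(sl[1])) as.numeric(sl[1])
    else max(positions)
  ref <- as.character(rr$REF)
  alt <- vapply(as.list(rr$ALT), function(a)
    paste(as.character(a), collapse = ","), character(1))
  info <- VariantAnnotation::info(vcf)
  anc <- if ("AA" %in% names(info)) {
    aa <- info$AA
    if (is.list(aa) || methods::is(aa, "List"))
      aa <- vapply(as.list(aa), function(v)
        if (length(v)) as.character(v[1]) else NA_character_, character(1))
    aa <- toupper(as.character(aa))
    aa[aa %in% c(".", "", "N", "NA")] <- NA_character_
    aa
  } else rep(NA_character_, length(positions))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  dec <- decode_gt(gt, multiallelic = grepl(",", alt, fixed = TRUE))
  codes <- dec$codes
  colnames(codes) <- colnames(gt)
  o <- order(positions)
  genotype_matrix(positions[o], ref[o], alt[o], anc[o],
                  codes[o, , drop = FALSE], region_length, region,
                  phased = dec$phased)
}

read_genotype_tsv <- function(path) {
  first <- readLines(path, n = 1)
  region <- "region1"; region_length <- NA_real_
  if (startsWith(first, "##")) {
    m <- regmatches(first, regexec("##region=([^;]+);length=([0-9.eE+]+)",
                                   first))[[1]]
    if (length(m) == 3) { region <- m[2]; region_length <- as.numeric(m[3]) }
  }
  df <- read.delim(path, comment.char = "",
                   skip = as.integer(startsWith(first, "##")),
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("pos", "ref", "alt", "aa")
  if (!all(need %in% names(df)))
    stop("genotype TSV must have columns pos, ref, alt, aa")
  samples <- setdiff(names(df), need)
  gt <- as.matrix(df[samples])
  dec <- decode_gt(gt, multiallelic = grepl(",", df$alt, fixed = TRUE))
  codes <- dec$codes
  colnames(codes) <- samples
  anc <- toupper(df$aa)
  anc[anc %in% c(".", "", "N")] <- NA_character_
  if (is.na(region_length)) region_length <- max(df$pos)
  o <- order(df$pos)
  genotype_matrix(df$pos[o], df$ref[o], df$alt[o], anc[o],
                  codes[o, , drop = FALSE], region_length, region,
                  phased = dec$phased)
}

#' Write a genotype matrix to VCF or TSV
#'
#' `write_genotype_vcf()` emits a minimal VCF 4.2 with the ancestral allele
#' in the `AA` INFO tag (`.` when unknown) and a contig line carrying the
#' region length, so that write-then-read round-trips exactly.
#'
#' @param x A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(x, path) {
  sep <- if (x$phased) "|" else "/"
  gcode <- c("0/0", "0/1", "1/1")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=coalsfs",
    sprintf("##contig=<ID=%s,length=%d>", x$region,
            as.integer(x$region_length)),
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(x)), collapse = "\t"))
  aa <- ifelse(is.na(x$ancestral), ".", x$ancestral)
  if (x$phased && !is.null(x$haplotypes)) {
    h <- x$haplotypes
    gt <- matrix(paste(h[, seq(1, ncol(h), 2), drop = FALSE],
                       h[, seq(2, ncol(h), 2), drop = FALSE], sep = "|"),
                 nrow = n_sites(x))
    gt[is.na(x$genotypes)] <- ".|."
  } else {
    gt <- matrix(gcode[x$genotypes + 1L], nrow = n_sites(x))
    gt[is.na(x$genotypes)] <- "./."
    if (x$phased) gt <- gsub("/", "|", gt, fixed = TRUE)
  }
  body <- paste(x$region, x$positions, ".", x$ref, x$alt, ".", "PASS",
                paste0("AA=", aa), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_genotype_vcf
#' @export
write_genotype_tsv <- function(x, path) {
  sep <- if (x$phased) "|" else "/"
  gcode <- paste(c(0, 0, 1), c(0, 1, 1), sep = sep)
  gt <- matrix(gcode[x$genotypes + 1L], nrow = n_sites(x))
  gt[is.na(x$genotypes)] <- paste(".", ".", sep = sep)
  df <- data.frame(pos = x$positions, ref = x$ref, alt = x$alt,
                   aa = ifelse(is.na(x$ancestral), ".", x$ancestral),
                   gt, check.names = FALSE)
  names(df)[-(1:4)] <- sample_ids(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##region=%s;length=%d", x$region,
                     as.integer(x$region_length)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_vcf
#' @param manifest A [sample_manifest()].
#' @export
write_manifest_tsv <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the standard report tables
#'
#' Emits tab-separated result tables: per-unit diversity statistics,
#' pairwise FST matrices (percent), fitted-parameter tables with bootstrap
#' CIs, and a machine-readable JSON fit summary.
#'
#' @param results A list with any of the elements `diversity` (data.frame),
#'   `fst_groups`, `fst_populations` (matrices), `fits` (list of
#'   `fit_result` objects), `pcoa` (a `pcoa_result`).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
write_report_tables <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to directory: ", out_dir)
  paths <- character(0)
  wt <- function(df, name, rn = FALSE) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = rn)
    paths <<- c(paths, p)
  }
  div <- results$diversity
  if (is.null(div))
    div <- data.frame(unit = character(), nInd = integer(), S = integer(),
                      Sp = integer(), theta = numeric(), pi = numeric(),
                      H = numeric(), HapHet = numeric(), TajimaD = numeric(),
                      P = numeric())
  wt(div, "diversity.tsv")
  for (nm in c("fst_groups", "fst_populations"))
    if (!is.null(results[[nm]]))
      wt(round(results[[nm]], 4), paste0(nm, ".tsv"), rn = TRUE)
  if (!is.null(results$pcoa)) {
    pc <- results$pcoa
    wt(data.frame(unit = rownames(pc$coordinates), pc$coordinates,
                  check.names = FALSE), "pcoa_coordinates.tsv")
  }
  if (!is.null(results$fits)) {
    fit_rows <- list()
    for (nm in names(results$fits)) {
      f <- results$fits[[nm]]
      tab <- fit_table(f)
      wt(tab, paste0("fit_", gsub("[^A-Za-z0-9_-]", "_", nm), ".tsv"))
      fit_rows[[nm]] <- list(parameters = as.list(setNames(tab$estimate,
                                                           tab$parameter)),
                             loglik = f$loglik, theta_hat = f$theta_hat)
    }
    p <- file.path(out_dir, "fit_summary.json")
    jsonlite::write_json(fit_rows, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  paths
}

# One row per parameter with estimate and bootstrap CI (NA when no CI).
fit_table <- function(fit) {
  est <- unlist(fit$params[param_names(fit$family)])
  ci <- fit$ci
  lo <- hi <- rep(NA_real_, length(est))
  if (!is.null(ci)) {
    m <- match(names(est), ci$parameter)
    lo <- ci$ci_low[m]; hi <- ci$ci_high[m]
  }
  data.frame(parameter = names(est), estimate = unname(est),
             CI_low = lo, CI_high = hi)
}
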