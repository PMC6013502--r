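#' Write genotypes as VCF 4.2
#'
#' GT-only VCF with 1-based positions; the simulation seed (when known)
#' is recorded in a header comment line.
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @param seed seed recorded in the header (taken from the attached
#'   config when available).
#' @export
write_vcf <- function(geno, path, seed = NULL) {
  if (is.null(seed)) {
    cfg <- attr(geno, "config")
    if (!is.null(cfg)) seed <- cfg$seed
  }
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               if (!is.null(seed)) paste0("##regmod_seed=", seed),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$sample_ids), collapse = "\t")),
             con)
  v <- geno$variants
  for (j in seq_len(nrow(v))) {
    d <- geno$dosages[, j]
    calls <- ifelse(is.na(d), "./.", gt[d + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                       v$alt[j], ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GT-style VCF into a genotype matrix
#'
#' Uses vcfR when available, otherwise a minimal parser for GT-only
#' files; alternate-allele dosages, `./.` treated as missing.
#'
#' @param path VCF path.
#' @return a [genotype_matrix()]; a `##regmod_seed` header line, when
#'   present, is attached as attribute `seed`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  seed_line <- grep("^##regmod_seed=", lines, value = TRUE)
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- vapply(seq_len(nrow(gt)), function(i) {
      g <- gt[i, ]
      out <- rep(NA_integer_, length(g))
      out[g %in% c("0/0", "0|0")] <- 0L
      out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
      out[g %in% c("1/1", "1|1")] <- 2L
      out
    }, integer(ncol(gt)))
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                           pos = as.numeric(fix$POS), ref = fix$REF,
                           alt = fix$ALT, stringsAsFactors = FALSE)
    g <- genotype_matrix(dos, variants, sample_ids = colnames(gt))
  } else {
    body <- lines[!startsWith(lines, "##")]
    header <- strsplit(body[1], "\t")[[1]]
    samples <- header[-(1:9)]
    rows <- strsplit(body[-1], "\t")
    variants <- data.frame(
      variant_id = vapply(rows, `[`, "", 3),
      chrom = vapply(rows, `[`, "", 1),
      pos = as.numeric(vapply(rows, `[`, "", 2)),
      ref = vapply(rows, `[`, "", 4), alt = vapply(rows, `[`, "", 5),
      stringsAsFactors = FALSE)
    dos <- vapply(rows, function(r) {
      g <- sub(":.*", "", r[-(1:9)])
      out <- rep(NA_integer_, length(g))
      out[g %in% c("0/0", "0|0")] <- 0L
      out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
      out[g %in% c("1/1", "1|1")] <- 2L
      out
    }, integer(length(samples)))
    g <- genotype_matrix(dos, variants, sample_ids = samples)
  }
  if (length(seed_line))
    attr(g, "seed") <- as.integer(sub("^##regmod_seed=", "", seed_line[1]))
  g
}

#' Write / read a dosage matrix as TSV
#'
#' Variants in rows (`variant_id`, `chrom`, `pos`, `ref`, `alt`, one
#' column per sample); the seed is carried in a leading comment line.
#'
#' @param geno a [genotype_matrix()].
#' @param path file path.
#' @export
write_dosage_tsv <- function(geno, path) {
  cfg <- attr(geno, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(paste0("# seed=", cfg$seed), con)
  df <- cbind(geno$variants[, c("variant_id", "chrom", "pos", "ref", "alt")],
              as.data.frame(t(geno$dosages)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("variant_id", "chrom", "pos", "ref", "alt")
  dos <- t(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]))
  genotype_matrix(dos, df[, meta], sample_ids = rownames(dos))
}

#' Write / read an expression matrix as TSV
#'
#' @param expr an [expression_matrix()].
#' @param path file path.
#' @param seed optional seed written in a comment line.
#' @export
write_expression_tsv <- function(expr, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  writeLines(paste0("# tissue=", expr$tissue), con)
  df <- cbind(expr$probes, as.data.frame(t(expr$values)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path, n = 5)
  tl <- grep("^# tissue=", lines, value = TRUE)
  tissue <- if (length(tl)) sub("^# tissue=", "", tl[1]) else "T1"
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("probe_id", "gene", "chrom", "pos")
  vals <- t(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]))
  expression_matrix(vals, df[, meta], tissue = tissue,
                    sample_ids = rownames(vals))
}

#' Write an association pattern as a summary-statistics TSV
#'
#' Columns `variant_id`, `chrom`, `pos`, `ref`, `alt`, `neg_log10_p`,
#' `sign` (the [association_pattern()] schema).
#'
#' @param pattern an [association_pattern()].
#' @param path file path.
#' @export
write_pattern_tsv <- function(pattern, path) {
  df <- pattern$variants[, c("variant_id", "chrom", "pos", "ref", "alt")]
  df$neg_log10_p <- pattern$neg_log10_p
  df$sign <- pattern$sign
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trait=%s anchor=%s:%d", pattern$trait,
                     pattern$anchor_chrom, as.integer(pattern$anchor_pos)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_tsv
#' @export
read_pattern_tsv <- function(path) {
  meta <- readLines(path, n = 1)
  trait <- sub("^# trait=([^ ]+).*", "\\1", meta)
  anchor <- sub(".*anchor=([^:]+):(\\d+).*", "\\1;\\2", meta)
  ap <- strsplit(anchor, ";")[[1]]
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  association_pattern(df[, c("variant_id", "chrom", "pos", "ref", "alt")],
                      df$neg_log10_p, df$sign, trait = trait,
                      anchor_chrom = ap[1], anchor_pos = as.numeric(ap[2]))
}

#' Read a risk-locus table
#'
#' Tab-separated `chrom`, `start`, `end`. Coordinates are 1-based
#' inclusive base pairs; `units = "Mb"` (or auto-detection of small
#' values) converts megabase coordinates as printed in locus tables to
#' the inclusive base-pair interval.
#'
#' @param path file path.
#' @param units `"auto"`, `"bp"` or `"Mb"`.
#' @return data frame `chrom`, `start`, `end` in bp.
#' @export
read_loci <- function(path, units = c("auto", "bp", "Mb")) {
  units <- match.arg(units)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("locus file must have columns chrom, start, end (",
         path, ")")
  bad <- which(is.na(df$start) | is.na(df$end) | df$end < df$start)
  if (length(bad))
    stop("malformed locus row ", bad[1] + 1, " in ", path)
  if (units == "auto") units <- if (max(df$end) < 1e4) "Mb" else "bp"
  if (units == "Mb") {
    df$start <- round(df$start * 1e6)
    df$end <- round(df$end * 1e6)
  }
  df[, c(need, setdiff(names(df), need))]
}
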