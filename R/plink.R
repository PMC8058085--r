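# PLINK 1 binary genotype input/output (SNP-major .bed with .bim/.fam),
# marker-group files, and the builtin MAF x LD-score grouper.

# 2-bit code -> A1 allele count: 00 hom-A1 = 2, 01 missing = NA,
# 10 het = 1, 11 hom-A2 = 0
.bed_decode <- c(2L, NA_integer_, 1L, 0L)

#' Read PLINK 1 binary genotypes
#'
#' Reads a SNP-major `.bed` (magic bytes `0x6C 0x1B 0x01`) with its `.bim`
#' and `.fam`, reporting counts of the A1 allele. Monomorphic or all-missing
#' markers are dropped with a message.
#'
#' @param prefix path prefix (without extension).
#' @return a [genotype_matrix()]; individual ids are kept in attribute
#'   `"fam"`.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE)
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  if (m == 0) stop("empty marker set")
  raw <- readBin(bed, "raw", n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (magic byte mismatch)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpm <- ceiling(n / 4)
  if (length(raw) != 3 + bpm * m)
    stop("truncated .bed: expected ", 3 + bpm * m, " bytes, got ", length(raw))
  body <- as.integer(raw[-(1:3)])
  # unpack all 4 two-bit fields of every byte, column-major per marker
  codes <- rbind(bitwAnd(body, 3L),
                 bitwAnd(bitwShiftR(body, 2L), 3L),
                 bitwAnd(bitwShiftR(body, 4L), 3L),
                 bitwAnd(bitwShiftR(body, 6L), 3L))
  dim(codes) <- c(4 * bpm, m)
  counts <- matrix(.bed_decode[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  g <- genotype_matrix(counts, ids = bim[[2]], chr = bim[[1]],
                       pos = bim[[4]], a1 = bim[[5]], a2 = bim[[6]])
  attr(g, "fam") <- fam
  g
}

#' Write PLINK 1 binary genotypes
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix; writes `.bed`, `.bim`, `.fam`.
#' @export
write_plink <- function(geno, prefix) {
  n <- geno$n; m <- geno$m
  counts <- geno_counts(geno)
  # A1 count -> 2-bit code
  code <- matrix(3L, n, m)                 # 0 copies of A1 -> hom-A2 (11)
  code[counts == 1] <- 2L                  # het (10)
  code[counts == 2] <- 0L                  # hom-A1 (00)
  code[is.na(counts)] <- 1L                # missing (01)
  bpm <- ceiling(n / 4)
  pad <- matrix(0L, 4 * bpm - n, m)        # zero-padding decodes as hom-A1,
  full <- rbind(code, pad)                 # but padded rows are never read
  dim(full) <- c(4, bpm * m)
  bytes <- full[1, ] + bitwShiftL(full[2, ], 2L) +
    bitwShiftL(full[3, ], 4L) + bitwShiftL(full[4, ], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  close(con)
  write.table(data.frame(geno$chr, geno$ids, 0, geno$pos, geno$a1, geno$a2),
              paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(seq_len(n), seq_len(n), 0, 0, 0, -9),
              paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a marker-to-group map
#'
#' Two-column whitespace-delimited text `marker_id group_label`. Every
#' retained marker must be assigned (or, with `missing = "drop"`, the
#' unassigned markers are reported back for removal); duplicate marker rows
#' are an error.
#'
#' @param path file path.
#' @param geno the [genotype_matrix()] the map must cover.
#' @param missing what to do with markers absent from the file: `"error"`
#'   (default) or `"drop"`.
#' @return list with `group` (vector aligned to `geno`, `NA` marks dropped
#'   markers) and `labels`.
#' @export
read_groups <- function(path, geno, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  tb <- read.table(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (anyDuplicated(tb[[1]])) stop("duplicate marker row in group file")
  idx <- match(geno$ids, tb[[1]])
  if (anyNA(idx) && missing == "error")
    stop("markers absent from group file: ",
         paste(head(geno$ids[is.na(idx)], 5), collapse = ", "))
  list(group = tb[[2]][idx], labels = unique(tb[[2]]))
}

#' Builtin MAF x LD-score marker groups
#'
#' Groups markers as MAF quantiles and then LD-score quantiles within each
#' MAF bin (the conventional 5 x 4 = 20-group layout). The LD score of a
#' marker is its sum of squared correlations with markers inside a physical
#' window; cut-points can be supplied directly to bypass the builtin
#' computation.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_bins,ld_bins numbers of quantile bins (defaults 5 and 4).
#' @param window_bp LD-score window (default 1 Mb).
#' @param maf_cuts,ld_cuts optional explicit cut-points overriding the
#'   quantiles (`ld_cuts` as a list, one vector per MAF bin).
#' @return integer group labels of length `m` (at most
#'   `maf_bins * ld_bins` distinct values).
#' @export
maf_ld_groups <- function(geno, maf_bins = 5, ld_bins = 4, window_bp = 1e6,
                          maf_cuts = NULL, ld_cuts = NULL) {
  maf <- pmin(geno$xbar / 2, 1 - geno$xbar / 2)
  Xs <- geno_std(geno)
  ldsc <- vapply(seq_len(geno$m), function(j) {
    wnd <- which(geno$chr == geno$chr[j] &
                   abs(geno$pos - geno$pos[j]) <= window_bp)
    r <- crossprod(Xs[, wnd, drop = FALSE], Xs[, j]) / (geno$n - 1)
    sum(r^2)
  }, numeric(1))
  if (is.null(maf_cuts))
    maf_cuts <- quantile(maf, seq_len(maf_bins - 1) / maf_bins)
  mg <- findInterval(maf, maf_cuts) + 1L
  grp <- integer(geno$m)
  for (b in sort(unique(mg))) {
    sel <- mg == b
    cuts <- if (is.null(ld_cuts)) {
      quantile(ldsc[sel], seq_len(ld_bins - 1) / ld_bins)
    } else ld_cuts[[b]]
    grp[sel] <- (b - 1L) * ld_bins + findInterval(ldsc[sel], cuts) + 1L
  }
  grp
}
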