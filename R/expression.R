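#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (length_bp * library_size)`.  Linear in the count,
#' inverse-linear in length and library size.
#'
#' @param count non-negative read count (vectorized).
#' @param length_bp transcript length in bp, positive.
#' @param library_size total mapped reads in the library, positive.
#' @return RPKM value(s).
#' @export
rpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count * 1e9 / (length_bp * library_size)
}

#' Two-condition expression table
#'
#' @param genes data.frame with `gene_id`, `length_bp`.
#' @param counts_a,counts_b integer count matrices (genes x replicates).
#' @param library_sizes list with numeric vectors `A` and `B` of total
#'   mapped reads per replicate.
#' @return an object of class `"gf_expression"`.
#' @export
expression_table <- function(genes, counts_a, counts_b, library_sizes) {
  stopifnot(is.data.frame(genes), all(c("gene_id", "length_bp") %in% names(genes)))
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(genes) || nrow(counts_b) != nrow(genes))
    stop("count matrices must have one row per gene")
  if (any(genes$length_bp <= 0)) stop("gene lengths must be positive")
  if (any(counts_a < 0) || any(counts_b < 0) ||
      any(counts_a != round(counts_a)) || any(counts_b != round(counts_b)))
    stop("counts must be non-negative integers")
  if (length(library_sizes$A) != ncol(counts_a) ||
      length(library_sizes$B) != ncol(counts_b))
    stop("library_sizes must match replicate counts")
  structure(list(genes = genes, counts_a = counts_a, counts_b = counts_b,
                 library_sizes = library_sizes),
            class = "gf_expression")
}

#' Threshold screen for differentially expressed genes
#'
#' A gene passes when its expression clears the abundance floor
#' (RPKM > `rpkm_min` in the more abundant condition, or in both with
#' `abundance = "both"`) and the fold change between condition means
#' exceeds 2 (strictly `|log2 FC| > log2fc_min`).  Replicates are
#' summarized by the arithmetic mean of per-replicate RPKM; a pseudocount
#' stabilizes the log ratio for zero-count genes.  Both inequalities are
#' strict.
#'
#' @param table an [expression_table()].
#' @param rpkm_min abundance floor (default 50 RPKM).
#' @param log2fc_min fold-change floor on the log2 scale (default 1).
#' @param eps pseudocount in RPKM units added before the log (default 0.01).
#' @param abundance `"max"` (default: the larger condition mean must clear
#'   the floor, so genes induced from near zero are retained) or `"both"`.
#' @return data.frame `gene_id`, `mean_rpkm_A`, `mean_rpkm_B`, `log2fc`,
#'   `direction` (`"up"`/`"down"` in B relative to A), sorted by |log2fc|
#'   descending with ties broken by gene id.
#' @export
screen_expression <- function(table, rpkm_min = 50, log2fc_min = 1,
                              eps = 0.01, abundance = c("max", "both")) {
  abundance <- match.arg(abundance)
  ra <- sweep(sweep(table$counts_a, 1, table$genes$length_bp, "/"),
              2, table$library_sizes$A, "/") * 1e9
  rb <- sweep(sweep(table$counts_b, 1, table$genes$length_bp, "/"),
              2, table$library_sizes$B, "/") * 1e9
  ma <- rowMeans(ra); mb <- rowMeans(rb)
  lfc <- log2(mb + eps) - log2(ma + eps)
  floor_ok <- if (abundance == "max") pmax(ma, mb) > rpkm_min
              else ma > rpkm_min & mb > rpkm_min
  hit <- floor_ok & abs(lfc) > log2fc_min
  out <- data.frame(gene_id = table$genes$gene_id[hit],
                    mean_rpkm_A = ma[hit], mean_rpkm_B = mb[hit],
                    log2fc = lfc[hit],
                    direction = ifelse(lfc[hit] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$log2fc), out$gene_id), , drop = FALSE]
}

#' Generate a synthetic two-condition expression table
#'
#' Negative-binomial counts around log-normal baseline abundances, with
#' `n_planted` genes given a true fold change (alternating up/down in B)
#' large enough to clear the default screen, at baseline expression above
#' the abundance floor.  Deterministic under the seed.  This is a synthetic
#' stand-in generator for testing the screen; it does not model any real
#' sequencing data set.
#'
#' @param n_genes total genes.
#' @param n_planted number of genes with a planted fold change
#'   (`<= n_genes`).
#' @param seed integer RNG seed.
#' @param baseline_params list overriding: `meanlog`/`sdlog` of baseline
#'   RPKM, `dispersion` (NB), `fold` (planted fold change), `n_reps`,
#'   `library_size`, `planted_rpkm_range`.
#' @return list with `table` (an [expression_table()]) and `truth`
#'   (data.frame of planted `gene_id`, `direction`, `fold`).
#' @export
generate_expression_table <- function(n_genes = 500, n_planted = 25,
                                      seed = 1L, baseline_params = list()) {
  if (n_planted > n_genes) stop("n_planted must not exceed n_genes")
  bp <- utils::modifyList(list(meanlog = log(20), sdlog = 1.2,
                               dispersion = 0.02, fold = 4, n_reps = 3,
                               library_size = 2e6,
                               planted_rpkm_range = c(100, 400)),
                          baseline_params)
  set.seed(seed)
  gene_id <- sprintf("gene_%04d", seq_len(n_genes))
  length_bp <- round(stats::runif(n_genes, 300, 3000))
  base_rpkm <- stats::rlnorm(n_genes, bp$meanlog, bp$sdlog)
  planted_idx <- if (n_planted > 0) sort(sample(n_genes, n_planted)) else integer(0)
  base_rpkm[planted_idx] <- stats::runif(n_planted, bp$planted_rpkm_range[1],
                                         bp$planted_rpkm_range[2])
  dir_up <- rep(c(TRUE, FALSE), length.out = n_planted)
  fold_b <- rep(1, n_genes)
  fold_b[planted_idx] <- ifelse(dir_up, bp$fold, 1 / bp$fold)
  # library sizes are the totals of the sequencing run; the simulated genes
  # are a subset of the transcriptome, so column sums of this table do not
  # define the library size
  libs_a <- round(bp$library_size * stats::runif(bp$n_reps, 0.95, 1.05))
  libs_b <- round(bp$library_size * stats::runif(bp$n_reps, 0.95, 1.05))
  draw <- function(rpkm_true, libs) {
    m <- matrix(0L, n_genes, bp$n_reps)
    for (r in seq_len(bp$n_reps)) {
      mu <- rpkm_true * length_bp * libs[r] / 1e9
      m[, r] <- stats::rnbinom(n_genes, mu = mu, size = 1 / bp$dispersion)
    }
    m
  }
  counts_a <- draw(base_rpkm, libs_a)
  counts_b <- draw(base_rpkm * fold_b, libs_b)
  tbl <- expression_table(
    data.frame(gene_id = gene_id, length_bp = length_bp,
               stringsAsFactors = FALSE),
    counts_a, counts_b, list(A = libs_a, B = libs_b))
  truth <- data.frame(gene_id = gene_id[planted_idx],
                      direction = ifelse(dir_up, "up", "down"),
                      fold = fold_b[planted_idx], stringsAsFactors = FALSE)
  list(table = tbl, truth = truth)
}

#' Write an expression table to TSV
#'
#' Format: a `# library_sizes:` comment row, then a header
#' `gene_id length_bp A_rep1.. B_rep1..` and one row per gene.
#'
#' @param table an [expression_table()].
#' @param path output file.
#' @export
write_expression_table <- function(table, path) {
  na <- ncol(table$counts_a); nb <- ncol(table$counts_b)
  cols_a <- paste0("A_rep", seq_len(na))
  cols_b <- paste0("B_rep", seq_len(nb))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# library_sizes: ",
                    paste(c(paste0(cols_a, "=", table$library_sizes$A),
                            paste0(cols_b, "=", table$library_sizes$B)),
                          collapse = " ")), con)
  df <- data.frame(gene_id = table$genes$gene_id,
                   length_bp = table$genes$length_bp)
  for (i in seq_len(na)) df[[cols_a[i]]] <- table$counts_a[, i]
  for (i in seq_len(nb)) df[[cols_b[i]]] <- table$counts_b[, i]
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression table from TSV
#' @param path file written by [write_expression_table()].
#' @return an [expression_table()].
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "# library_sizes:"))
    stop("expression file must start with a '# library_sizes:' comment row")
  kv <- strsplit(trimws(sub("^# library_sizes:", "", lines[1])), " +")[[1]]
  parts <- strsplit(kv, "=", fixed = TRUE)
  libs <- vapply(parts, function(p) as.numeric(p[2]), 0)
  names(libs) <- vapply(parts, `[[`, "", 1)
  df <- utils::read.table(text = paste(lines[-1], collapse = "\n"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("gene_id", "length_bp"))
    if (!col %in% names(df)) stop("missing column '", col, "'")
  cols_a <- grep("^A_rep", names(df), value = TRUE)
  cols_b <- grep("^B_rep", names(df), value = TRUE)
  if (length(cols_a) == 0 || length(cols_b) == 0)
    stop("missing replicate count columns (A_rep*/B_rep*)")
  expression_table(df[, c("gene_id", "length_bp")],
                   as.matrix(df[, cols_a, drop = FALSE]),
                   as.matrix(df[, cols_b, drop = FALSE]),
                   list(A = unname(libs[cols_a]), B = unname(libs[cols_b])))
}
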