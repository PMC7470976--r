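## Expression-presence rules over an FPKM matrix with (tissue, stage, sex,
## replicate) sample metadata: per-condition and per-tissue expression,
## tissue specificity, housekeeping sets, and dominant-isoform switching.

#' Construct an expression matrix with sample metadata
#'
#' @param values numeric matrix, features x samples, FPKM (>= 0); row names
#'   are feature ids, column names are sample ids
#' @param meta data.frame with columns `sample`, `tissue`, `stage`, `sex`,
#'   `replicate`; one row per column of `values`, (tissue, stage, sex,
#'   replicate) unique
#' @param level `"gene"` or `"transcript"`
#' @return object of class `ExpressionMatrix`
#' @export
new_expression_matrix <- function(values, meta, level = c("transcript", "gene")) {
  level <- match.arg(level)
  meta <- data.table::as.data.table(meta)
  req <- c("sample", "tissue", "stage", "sex", "replicate")
  if (!all(req %in% names(meta))) stop2("meta lacks column(s): %s",
                                        paste(setdiff(req, names(meta)), collapse = ", "))
  if (is.null(colnames(values)) || is.null(rownames(values)))
    stop2("values must have row and column names")
  if (!setequal(colnames(values), meta$sample)) stop2("meta does not cover all samples")
  if (anyDuplicated(meta[, .(tissue, stage, sex, replicate)]))
    stop2("(tissue, stage, sex, replicate) combinations must be unique")
  if (any(values < 0)) stop2("negative FPKM values")
  meta <- meta[match(colnames(values), sample)]
  structure(list(values = values, meta = meta, level = level), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s level): %d features x %d samples, %d tissues, %d stages\n",
              x$level, nrow(x$values), ncol(x$values),
              data.table::uniqueN(x$meta$tissue), data.table::uniqueN(x$meta$stage)))
  invisible(x)
}

#' Per-condition expression calls
#'
#' A feature is expressed in a biological condition (a tissue-stage pair;
#' sexes pooled by default) iff at least `min_samples` of the condition's
#' samples have FPKM strictly greater than `fpkm_min`.  Conditions with
#' fewer than `min_samples` total samples are evaluated on the available
#' samples and flagged.
#'
#' @param m an `ExpressionMatrix`
#' @param fpkm_min FPKM threshold (strict `>`), default 0.5
#' @param min_samples minimum passing samples, default 2
#' @param by_sex split conditions by sex as well (default `FALSE`: the
#'   condition grid pools sexes, giving tissues x stages conditions)
#' @return logical matrix features x conditions (condition names
#'   `tissue|stage` or `tissue|stage|sex`); attributes `condition_meta`
#'   (tissue/stage per condition) and `underpowered` (flagged conditions)
#' @export
expressed_in_condition <- function(m, fpkm_min = 0.5, min_samples = 2L, by_sex = FALSE) {
  meta <- m$meta
  cond <- if (by_sex) paste(meta$tissue, meta$stage, meta$sex, sep = "|")
          else paste(meta$tissue, meta$stage, sep = "|")
  conds <- sort(unique(cond))
  pass <- m$values > fpkm_min
  out <- matrix(FALSE, nrow(m$values), length(conds),
                dimnames = list(rownames(m$values), conds))
  under <- character()
  for (cd in conds) {
    cols <- which(cond == cd)
    if (length(cols) < min_samples) under <- c(under, cd)
    out[, cd] <- rowSums(pass[, cols, drop = FALSE]) >= min_samples
  }
  cm <- data.table::data.table(condition = conds,
                               tissue = sub("\\|.*$", "", conds))
  data.table::setattr(out, "condition_meta", cm)
  data.table::setattr(out, "underpowered", under)
  if (length(under)) warn2("condition(s) with fewer than %d samples: %s",
                           min_samples, paste(under, collapse = ", "))
  out
}

#' Per-tissue expression calls
#'
#' A feature is expressed in a tissue iff it is expressed in at least one
#' of the tissue's conditions (logical OR over stages).
#'
#' @param cond_table logical matrix from [expressed_in_condition()]
#' @return logical matrix features x tissues
#' @export
expressed_in_tissue <- function(cond_table) {
  tis <- sub("\\|.*$", "", colnames(cond_table))
  tissues <- sort(unique(tis))
  out <- matrix(FALSE, nrow(cond_table), length(tissues),
                dimnames = list(rownames(cond_table), tissues))
  for (t in tissues)
    out[, t] <- rowSums(cond_table[, tis == t, drop = FALSE]) > 0L
  out
}

#' Tissue-specificity partition
#'
#' @param tissue_table logical matrix from [expressed_in_tissue()]
#' @return list with `per_tissue` (data.table `tissue`, `unique`, `common`:
#'   features expressed only there vs. there and in >= 1 other tissue) and
#'   `feature_class` (per feature: number of expressing tissues)
#' @export
specificity_partition <- function(tissue_table) {
  ntis <- rowSums(tissue_table)
  per <- data.table::rbindlist(lapply(colnames(tissue_table), function(t) {
    inT <- tissue_table[, t]
    data.table::data.table(tissue = t,
                           unique = sum(inT & ntis == 1L),
                           common = sum(inT & ntis > 1L))
  }))
  list(per_tissue = per,
       feature_class = data.table::data.table(feature = rownames(tissue_table),
                                              n_tissues = ntis))
}

#' Housekeeping features
#'
#' Features expressed in every tissue of the panel (logical AND).
#'
#' @param tissue_table logical matrix from [expressed_in_tissue()] with at
#'   least 2 tissues
#' @return character vector of housekeeping feature ids
#' @export
housekeeping <- function(tissue_table) {
  if (ncol(tissue_table) < 2L) stop2("housekeeping requires >= 2 tissues")
  rownames(tissue_table)[rowSums(tissue_table) == ncol(tissue_table)]
}

#' Genes whose dominant isoform switches between tissues
#'
#' The dominant isoform of a gene in a tissue is the transcript with the
#' highest mean FPKM over the tissue's samples (ties broken by the
#' lexicographically smallest transcript id, flagged).  A gene is reported
#' iff its dominant isoform differs between at least two tissues in which
#' the gene is expressed (any isoform expressed under the condition rule).
#'
#' @param m transcript-level `ExpressionMatrix`
#' @param a `Annotation` providing the transcript-to-gene mapping
#' @param genes optional gene subset (e.g. housekeeping genes)
#' @param fpkm_min,min_samples expression-rule parameters (see
#'   [expressed_in_condition()])
#' @return list with `switching` (character vector of reported gene ids)
#'   and `table` (per gene x tissue: dominant isoform, mean FPKM, tie flag)
#' @export
dominant_isoform_switches <- function(m, a, genes = NULL, fpkm_min = 0.5, min_samples = 2L) {
  stopifnot(m$level == "transcript")
  t2g <- setNames(a$tx$gene_id, a$tx$transcript_id)
  feats <- intersect(rownames(m$values), names(t2g))
  if (!is.null(genes)) feats <- feats[t2g[feats] %in% genes]
  if (!length(feats)) return(list(switching = character(), table = data.table::data.table()))
  expr_t <- expressed_in_tissue(expressed_in_condition(m, fpkm_min, min_samples))
  tissues <- sort(unique(m$meta$tissue))
  rows <- list()
  for (tis in tissues) {
    cols <- m$meta$sample[m$meta$tissue == tis]
    mu <- rowMeans(m$values[feats, cols, drop = FALSE])
    dt <- data.table::data.table(transcript_id = feats, gene_id = t2g[feats], mean_fpkm = mu,
                                 expressed = expr_t[feats, tis])
    dom <- dt[, {
      o <- order(-mean_fpkm, transcript_id)
      .(dominant = transcript_id[o[1L]], mean_fpkm = mean_fpkm[o[1L]],
        tie = .N > 1L && sum(mean_fpkm == max(mean_fpkm)) > 1L,
        gene_expressed = any(expressed))
    }, by = gene_id]
    rows[[tis]] <- data.table::data.table(tissue = tis, dom)
  }
  tab <- data.table::rbindlist(rows)
  multi <- names(which(table(t2g[feats]) >= 2L))
  sw <- tab[gene_id %in% multi & gene_expressed == TRUE,
            .(n_dom = data.table::uniqueN(dominant), n_tissues = .N), by = gene_id]
  list(switching = sort(sw[n_dom >= 2L & n_tissues >= 2L]$gene_id), table = tab)
}
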