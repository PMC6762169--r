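#' Hierarchically cluster samples on a gene signature
#'
#' Samples are clustered agglomeratively on their signature-gene expression
#' vectors using Euclidean distance, and the dendrogram is cut at the root
#' (the last merge) into exactly two groups. Residual below-detection cells
#' among the signature genes are imputed with the gene's across-sample mean
#' of detected values before distances are computed — the detection filter
#' guarantees missingness is mild, so this imputation is a small
#' perturbation. Genes are not rescaled by default (log ratios share a
#' scale); `rescale = TRUE` standardises each gene to unit SD.
#'
#' @param x an [expr_matrix].
#' @param genes signature gene ids to cluster on (default: all genes of
#'   `x`). Must be non-empty.
#' @param linkage agglomeration rule: `"average"` (UPGMA, the default),
#'   `"complete"`, `"ward"` (Ward on Euclidean distances, i.e. `ward.D2`),
#'   or `"single"`.
#' @param rescale standardise each gene to unit SD before clustering.
#' @return An object of class `"cluster_assignment"`: list with `hclust`
#'   (the merge tree; heights in Euclidean distance units), `cluster`
#'   (integer 1/2 per sample, input order), `linkage`, and — after
#'   [label_groups()] — `group_of` (`"A"`/`"B"` per sample).
#' @examples
#' ds <- simulate_expression(sim_config(n_genes = 100, n_signature = 20,
#'                                      effect_size = 5, noise_sd = 0.3))
#' ca <- cluster_samples(ds$expression, genes = ds$truth)
#' table(ca$cluster)
#' @export
cluster_samples <- function(x, genes = NULL,
                            linkage = c("average", "complete", "ward", "single"),
                            rescale = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  linkage <- match.arg(linkage)
  if (is.null(genes)) genes <- gene_ids(x)
  if (length(genes) == 0L) stop("empty gene signature")
  missing_genes <- setdiff(genes, gene_ids(x))
  if (length(missing_genes))
    stop("signature genes absent from matrix: ",
         paste(utils::head(missing_genes, 3L), collapse = ", "))
  if (ncol(x$values) < 2L) stop("need at least 2 samples to cluster")
  sub <- x[genes, , drop = FALSE]
  v <- impute_below_detection(sub)
  if (rescale) {
    sds <- apply(v, 1L, stats::sd)
    if (any(sds == 0)) stop("cannot rescale a constant gene")
    v <- v / sds
  }
  hc <- stats::hclust(stats::dist(t(v), method = "euclidean"),
                      method = if (linkage == "ward") "ward.D2" else linkage)
  cl <- stats::cutree(hc, k = 2L)
  structure(list(hclust = hc, cluster = cl, linkage = linkage,
                 genes = genes, group_of = NULL),
            class = "cluster_assignment")
}

# Replace masked cells by the gene's mean over detected values (all samples).
impute_below_detection <- function(x) {
  v <- x$values
  v[x$below_detection] <- NA
  n_det <- rowSums(!x$below_detection)
  if (any(n_det == 0L))
    stop("gene with no detected values cannot be imputed: ",
         gene_ids(x)[n_det == 0L][1])
  means <- rowMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- means[idx[, 1L]]
  v
}

#' Identify the LVSI-enriched cluster as group A
#'
#' Group A is the cluster with the higher proportion of LVSI-positive
#' samples; it plays the role of the "test positive" call. Ties are broken
#' by the higher absolute positive count, then by the cluster containing
#' the first sample in input order.
#'
#' @param assignment a `"cluster_assignment"` from [cluster_samples()].
#' @param labels LVSI labels (see [detection_filter()] for accepted forms),
#'   aligned with the clustered samples.
#' @return The assignment with `group_of` filled (`"A"`/`"B"` per sample).
#' @export
label_groups <- function(assignment, labels) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cl <- assignment$cluster
  pos <- lvsi_logical(labels)
  if (!is.null(names(pos))) {
    if (!all(names(cl) %in% names(pos)))
      stop("labels missing for samples: ",
           paste(setdiff(names(cl), names(pos)), collapse = ", "))
    pos <- pos[names(cl)]
  } else if (length(pos) != length(cl)) {
    stop("unnamed labels must match the number of clustered samples")
  }
  npos <- tapply(pos, cl, sum)
  size <- tapply(pos, cl, length)
  prop <- npos / size
  a <- if (prop[["1"]] != prop[["2"]]) {
    if (prop[["1"]] > prop[["2"]]) 1L else 2L
  } else if (npos[["1"]] != npos[["2"]]) {
    if (npos[["1"]] > npos[["2"]]) 1L else 2L
  } else {
    cl[[1L]]  # tie: the cluster holding the first sample in input order
  }
  assignment$group_of <- stats::setNames(ifelse(cl == a, "A", "B"), names(cl))
  assignment
}

#' Predict LVSI status from cluster membership
#'
#' Group A members are called LVSI-positive, group B members LVSI-negative.
#'
#' @param object a labelled `"cluster_assignment"` (after [label_groups()]).
#' @param ... unused.
#' @return Named character vector, `"positive"`/`"negative"` per sample.
#' @export
predict.cluster_assignment <- function(object, ...) {
  if (is.null(object$group_of))
    stop("groups not labelled; call label_groups() first")
  stats::setNames(ifelse(object$group_of == "A", "positive", "negative"),
                  names(object$group_of))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples, %s linkage, groups %s\n",
              length(x$cluster), x$linkage,
              if (is.null(x$group_of)) "unlabelled"
              else paste(table(x$group_of), collapse = "/")))
  invisible(x)
}

#' Serialise a dendrogram as Newick
#'
#' Converts the merge tree to a phylogeny (branch lengths derived from the
#' merge heights, Euclidean distance units) and writes Newick text.
#'
#' @param assignment a `"cluster_assignment"`.
#' @param path output path; `NULL` returns the Newick string.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_dendrogram <- function(assignment, path = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  phy <- ape::as.phylo(assignment$hclust)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write the two-group assignment table
#'
#' @param assignment a labelled `"cluster_assignment"`.
#' @param path output path for a two-column tab-delimited file
#'   (`sample_id`, `group`).
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path, header = NULL) {
  if (is.null(assignment$group_of))
    stop("groups not labelled; call label_groups() first")
  df <- data.frame(sample_id = names(assignment$group_of),
                   group = unname(assignment$group_of))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heat map of samples by signature genes
#'
#' Convenience plot mirroring the usual signature heat map: signature genes
#' in rows, samples in columns, columns annotated by cluster group.
#'
#' @param x an [expr_matrix].
#' @param assignment a labelled `"cluster_assignment"` on `x`'s samples.
#' @param ... passed to [stats::heatmap()].
#' @return Invisibly, the imputed matrix that was drawn.
#' @export
plot_signature_heatmap <- function(x, assignment, ...) {
  stopifnot(inherits(x, "expr_matrix"),
            inherits(assignment, "cluster_assignment"))
  v <- impute_below_detection(x[assignment$genes, , drop = FALSE])
  side <- if (!is.null(assignment$group_of))
    ifelse(assignment$group_of[colnames(v)] == "A", "firebrick", "steelblue")
  else rep("grey", ncol(v))
  stats::heatmap(v, ColSideColors = side, scale = "none",
                 col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(v)
}
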