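#' Build the gene x individual call matrix of one family
#'
#' Rows are the union of genes called CNV in at least one individual of
#' the family; columns are the tested individuals (every individual with
#' at least one call record, whether positive or not). Direction and PAV
#' status are carried along as attributes.
#'
#' @param calls data.frame of gene calls (as from [call_array()],
#'   possibly several arrays row-bound).
#' @param metadata data.frame mapping `array_id` to `test_sample` and
#'   `family_id` (see [array_metadata()]).
#' @return Logical matrix of class `call_matrix` (genes x individuals)
#'   with attributes `family_id`, `direction` (character matrix) and
#'   `pav` (logical matrix).
#' @export
build_call_matrix <- function(calls, metadata) {
  validate_calls(calls)
  require_cols(metadata, c("array_id", "test_sample", "family_id"),
               "array metadata")
  idx <- match(calls$array_id, metadata$array_id)
  if (anyNA(idx)) abort("calls reference arrays absent from metadata")
  fam <- unique(metadata$family_id[idx])
  if (length(fam) > 1)
    abort("calls span multiple families: %s", paste(fam, collapse = ", "))
  ind <- metadata$test_sample[idx]
  individuals <- unique(ind)
  genes <- sort(unique(calls$gene_id[calls$is_cnv]))

  mat <- matrix(FALSE, nrow = length(genes), ncol = length(individuals),
                dimnames = list(genes, individuals))
  dir <- matrix("none", nrow = length(genes), ncol = length(individuals),
                dimnames = list(genes, individuals))
  pav <- matrix(FALSE, nrow = length(genes), ncol = length(individuals),
                dimnames = list(genes, individuals))
  hit <- calls$is_cnv & calls$gene_id %in% genes
  if (any(hit)) {
    cells <- cbind(match(calls$gene_id[hit], genes),
                   match(ind[hit], individuals))
    mat[cells] <- TRUE
    dir[cells] <- calls$direction[hit]
    pav[cells] <- calls$is_pav[hit]
  }
  structure(mat, class = c("call_matrix", "matrix"),
            family_id = if (length(fam)) fam else NA_character_,
            direction = dir, pav = pav)
}

#' Per-gene carrier counts of a call matrix
#' @param matrix A `call_matrix`.
#' @return Named integer vector (genes).
#' @export
carrier_counts <- function(matrix) {
  stopifnot(inherits(matrix, "call_matrix"))
  rowSums(matrix)
}

#' Per-individual CNV counts of a call matrix
#' @param matrix A `call_matrix`.
#' @return Named integer vector (individuals).
#' @export
individual_counts <- function(matrix) {
  stopifnot(inherits(matrix, "call_matrix"))
  colSums(matrix)
}

#' Classify gene CNVs as common or infrequent
#'
#' A gene CNV is infrequent when exactly one individual of the family
#' carries it and common when two or more do. Percentages of each class,
#' and of presence/absence variants among the called genes, are the
#' family summary columns reported for pedigree studies.
#'
#' @param matrix A `call_matrix`.
#' @return List with `classes` (data.frame `gene_id`, `carriers`,
#'   `class`), `pct_common`, `pct_infrequent`, `pct_pav`.
#' @export
classify_frequency <- function(matrix) {
  stopifnot(inherits(matrix, "call_matrix"))
  cc <- carrier_counts(matrix)
  if (!length(cc))
    return(list(classes = data.frame(gene_id = character(),
                                     carriers = integer(),
                                     class = character()),
                pct_common = NA_real_, pct_infrequent = NA_real_,
                pct_pav = NA_real_))
  cls <- ifelse(cc == 1, "infrequent", "common")
  pav <- attr(matrix, "pav")
  gene_pav <- rowSums(pav) > 0
  list(classes = data.frame(gene_id = names(cc),
                            carriers = as.integer(cc), class = cls,
                            stringsAsFactors = FALSE, row.names = NULL),
       pct_common = 100 * mean(cls == "common"),
       pct_infrequent = 100 * mean(cls == "infrequent"),
       pct_pav = 100 * mean(gene_pav))
}

#' Flag outlier individuals by CNV count
#'
#' An individual is an outlier when its CNV count exceeds the family
#' mean by more than two family standard deviations.
#'
#' @param matrix A `call_matrix`.
#' @return data.frame `individual`, `n_cnv`, `outlier`.
#' @export
flag_outliers <- function(matrix) {
  n <- individual_counts(matrix)
  thr <- mean(n) + 2 * stats::sd(n)
  data.frame(individual = names(n), n_cnv = as.integer(n),
             outlier = n > thr, stringsAsFactors = FALSE, row.names = NULL)
}

# Coerce a per-family input (call_matrix or character vector) to a gene
# set: the union over individuals.
family_gene_set <- function(x) {
  if (inherits(x, "call_matrix")) rownames(x)[rowSums(x) > 0]
  else as.character(x)
}

#' Shared and core gene CNV sets across families
#'
#' Per family the gene set is the union over its individuals. Reports the
#' pairwise intersection counts, the core set present in every family,
#' the union, and the genes exclusive to each family.
#'
#' @param matrices Named list (>= 2 entries) of `call_matrix` objects or
#'   character vectors of gene ids.
#' @return List with `sets`, `pairwise` (symmetric count matrix), `core`,
#'   `union_size`, `exclusive`.
#' @export
share_sets <- function(matrices) {
  if (length(matrices) < 2) abort("share_sets needs at least two families")
  if (is.null(names(matrices)))
    names(matrices) <- paste0("family", seq_along(matrices))
  sets <- lapply(matrices, family_gene_set)
  fam <- names(sets)
  pw <- matrix(0L, length(fam), length(fam), dimnames = list(fam, fam))
  for (i in seq_along(fam))
    for (j in seq_along(fam))
      pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  core <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  exclusive <- lapply(seq_along(sets), function(i)
    setdiff(sets[[i]], Reduce(union, sets[-i])))
  names(exclusive) <- fam
  list(sets = sets, pairwise = pw, core = sort(core),
       union_size = length(uni), exclusive = exclusive)
}

#' Compare per-individual CNV counts between families
#'
#' One-way ANOVA on the per-individual CNV counts grouped by family,
#' followed by Tukey honest-significant-difference pairwise comparisons
#' with adjusted p-values. When all counts are identical (zero total
#' variance) the F statistic is reported as 0 and no pair is significant.
#'
#' @param counts data.frame with columns `family`, `individual`, `n_cnv`
#'   (>= 2 families with >= 2 individuals each).
#' @return List with `anova_f`, `anova_p`, and `tukey`: data.frame
#'   `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
compare_family_counts <- function(counts) {
  require_cols(counts, c("family", "individual", "n_cnv"), "count table")
  counts$family <- factor(counts$family)
  if (nlevels(counts$family) < 2)
    abort("need at least two families")
  if (any(table(counts$family) < 2))
    abort("each family needs at least two individuals")
  if (stats::sd(counts$n_cnv) < 1e-12) {
    pairs <- utils::combn(levels(counts$family), 2,
                          FUN = paste, collapse = "-")
    return(list(anova_f = 0, anova_p = 1,
                tukey = data.frame(pair = pairs, diff = 0, lwr = 0,
                                   upr = 0, p_adj = 1,
                                   stringsAsFactors = FALSE)))
  }
  fit <- stats::aov(n_cnv ~ family, data = counts)
  sm <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit)$family
  list(anova_f = sm[["F value"]][1], anova_p = sm[["Pr(>F)"]][1],
       tukey = data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                          lwr = hsd[, "lwr"], upr = hsd[, "upr"],
                          p_adj = hsd[, "p adj"], stringsAsFactors = FALSE,
                          row.names = NULL))
}

#' Genetic-map distribution report for gene CNVs
#'
#' Restricts the CNV gene sets to genes with a map position and reports:
#' per-linkage-group CNV counts (over the pooled set), the mean distance
#' between consecutive mapped CNV genes per family (gaps pooled across
#' linkage groups, never spanning two groups), clusters of two or more
#' mapped CNV genes with consecutive gaps at most `cluster_window` cM,
#' and a two-sample Kolmogorov-Smirnov comparison of the positions of CNV
#' genes against all mapped genes (positions min-max scaled to [0, 1]
#' within each linkage group before pooling).
#'
#' @param family_sets Named list of `call_matrix` objects or character
#'   vectors of CNV gene ids, one per family.
#' @param map A [genetic_map()].
#' @param cluster_window Maximum chained gap within a cluster, in cM.
#' @return List with `per_lg`, `mean_adjacent` (per family, cM),
#'   `clusters` (data.frame), `ks` (statistic and p-value), `n_mapped`,
#'   `n_unmapped`.
#' @export
map_report <- function(family_sets, map, cluster_window = 1.0) {
  stopifnot(inherits(map, "genetic_map"))
  sets <- lapply(family_sets, family_gene_set)
  pooled <- sort(unique(unlist(sets)))
  mapped <- intersect(pooled, map$gene_id)
  if (length(mapped) < 2)
    abort("map positions available for fewer than 2 called genes")
  n_unmapped <- length(pooled) - length(mapped)

  pos_of <- function(genes) {
    i <- match(genes, map$gene_id)
    data.frame(gene_id = genes, lg = map$linkage_group[i],
               pos = map$position[i], stringsAsFactors = FALSE)
  }
  pm <- pos_of(mapped)
  per_lg <- as.data.frame(table(lg = pm$lg), stringsAsFactors = FALSE)
  names(per_lg) <- c("linkage_group", "n_cnv")

  adjacent_gaps <- function(genes) {
    d <- pos_of(intersect(genes, map$gene_id))
    unlist(lapply(split(d$pos, d$lg), function(p)
      if (length(p) >= 2) diff(sort(p)) else numeric(0)), use.names = FALSE)
  }
  mean_adjacent <- vapply(sets, function(s) {
    gaps <- adjacent_gaps(s)
    if (length(gaps)) mean(gaps) else NA_real_
  }, numeric(1))

  clusters <- do.call(rbind, lapply(split(pm, pm$lg), function(d) {
    d <- d[order(d$pos), ]
    if (nrow(d) < 2) return(NULL)
    grp <- cumsum(c(1, diff(d$pos) > cluster_window))
    sizes <- table(grp)
    keep <- names(sizes)[sizes >= 2]
    if (!length(keep)) return(NULL)
    do.call(rbind, lapply(keep, function(k) {
      sub <- d[grp == k, ]
      data.frame(linkage_group = sub$lg[1], n_genes = nrow(sub),
                 start_cm = min(sub$pos), end_cm = max(sub$pos),
                 genes = paste(sub$gene_id, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(clusters))
    clusters <- data.frame(linkage_group = character(),
                           n_genes = integer(), start_cm = numeric(),
                           end_cm = numeric(), genes = character())
  rownames(clusters) <- NULL

  scale_pos <- function(d) {
    rng <- tapply(map$position, map$linkage_group, range)
    vapply(seq_len(nrow(d)), function(i) {
      r <- rng[[d$lg[i]]]
      if (diff(r) < 1e-12) 0.5 else (d$pos[i] - r[1]) / diff(r)
    }, numeric(1))
  }
  all_pos <- data.frame(gene_id = map$gene_id, lg = map$linkage_group,
                        pos = map$position, stringsAsFactors = FALSE)
  ks <- suppressWarnings(stats::ks.test(scale_pos(pm), scale_pos(all_pos)))

  list(per_lg = per_lg, mean_adjacent = mean_adjacent, clusters = clusters,
       ks = list(statistic = unname(ks$statistic), p_value = ks$p.value),
       n_mapped = length(mapped), n_unmapped = n_unmapped)
}
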