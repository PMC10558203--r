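#' Nonparametric two-group comparison
#'
#' Wilcoxon rank-sum (unpaired) or signed-rank (paired) test, two-sided.
#' The exact null distribution is used for small samples (unpaired: both
#' n <= 10; paired: n <= 15) when the data are tie-free; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param a,b numeric samples; for `mode = "paired"` they must have equal
#'   length >= 2.
#' @param mode `"unpaired"` (rank sum) or `"paired"` (signed rank).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` (default) chooses by sample size.
#' @return A `group_comparison`: list with `test`, `statistic`, `p_value`,
#'   `n`, `exact`; degenerate paired input (all differences zero) returns
#'   `p_value = NULL` with a `reason`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p_value  # exact two-sided 0.1
#' @export
compare_groups <- function(a, b, mode = c("unpaired", "paired"),
                           exact = NULL) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (mode == "unpaired") {
    if (length(a) == 0 || length(b) == 0) {
      stop("both groups must be non-empty", call. = FALSE)
    }
    if (is.null(exact)) exact <- length(a) <= 10 && length(b) <= 10
    test_name <- "rank-sum"
  } else {
    if (length(a) != length(b) || length(a) < 2) {
      stop("paired mode needs equal lengths >= 2", call. = FALSE)
    }
    if (all(a == b)) {
      return(structure(list(test = "signed-rank", statistic = NA_real_,
                            p_value = NULL, n = c(length(a), length(b)),
                            exact = NA,
                            reason = "all paired differences are zero"),
                       class = "group_comparison"))
    }
    if (is.null(exact)) exact <- length(a) <= 15
    test_name <- "signed-rank"
  }
  ht <- suppressWarnings(wilcox.test(
    a, b, paired = (mode == "paired"), exact = exact, correct = TRUE,
    alternative = "two.sided"))
  used_exact <- exact && !grepl("correction", ht$method)
  structure(list(test = test_name, statistic = unname(ht$statistic),
                 p_value = ht$p.value, n = c(length(a), length(b)),
                 exact = used_exact, reason = NULL),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (is.null(x$p_value)) {
    cat("Wilcoxon", x$test, "test: no result (", x$reason, ")\n")
  } else {
    cat(sprintf("Wilcoxon %s test: W = %g, p = %.3g (%s), n = %d vs %d\n",
                x$test, x$statistic, x$p_value,
                if (isTRUE(x$exact)) "exact" else "normal approximation",
                x$n[1], x$n[2]))
  }
  invisible(x)
}

#' Pair soma and dendrite kinetics
#'
#' Assembles a paired table of kinetics for each (soma, dendrite) pair in an
#' ROI set, using the dendrites' parent links; ROIs without a partner are
#' listed separately.
#'
#' @param results named list of per-ROI kinetics (e.g. from [roi_kinetics()]),
#'   names being ROI labels.
#' @param rois an [roi_set()].
#' @return List with `paired` (one row per soma-dendrite pair, both
#'   half-times) and `unpaired` (data frame of unmatched ROIs).
#' @export
dendrite_soma_report <- function(results, rois) {
  cats <- rois$categories
  dendrites <- cats[cats$category == "dendrite", , drop = FALSE]
  somas <- cats[cats$category == "soma", , drop = FALSE]
  if (nrow(dendrites) > 0) {
    dangling <- !dendrites$parent %in% somas$label
    if (any(dangling)) {
      stop("dendrite ROI ", paste(dendrites$label[dangling], collapse = ", "),
           " references a missing soma", call. = FALSE)
    }
  }
  getk <- function(lab, field) {
    r <- results[[as.character(lab)]]
    if (is.null(r) || is.null(r[[field]])) NA_real_ else r[[field]]
  }
  paired <- do.call(rbind, lapply(seq_len(nrow(dendrites)), function(i) {
    d <- dendrites[i, ]
    data.frame(soma = d$parent, dendrite = d$label,
               t_half_acid_soma = getk(d$parent, "t_half_acid"),
               t_half_acid_dendrite = getk(d$label, "t_half_acid"),
               t_half_rec_soma = getk(d$parent, "t_half_rec"),
               t_half_rec_dendrite = getk(d$label, "t_half_rec"))
  }))
  if (is.null(paired)) {
    paired <- data.frame(soma = integer(0), dendrite = integer(0),
                         t_half_acid_soma = numeric(0),
                         t_half_acid_dendrite = numeric(0),
                         t_half_rec_soma = numeric(0),
                         t_half_rec_dendrite = numeric(0))
  }
  matched <- c(paired$soma, paired$dendrite)
  unpaired <- cats[!cats$label %in% matched, c("label", "category"),
                   drop = FALSE]
  rownames(unpaired) <- NULL
  list(paired = paired, unpaired = unpaired)
}
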