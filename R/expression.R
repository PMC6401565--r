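#' Construct an expression matrix with two-group labels
#'
#' Container for a normalized gene-expression matrix (genes in rows, samples
#' in columns) together with a case/control label per sample. This is the
#' input of the differential-expression stage; upstream array preprocessing
#' (background correction, normalization, probe-to-gene collapsing) is
#' assumed already done.
#'
#' @param values Numeric matrix, genes x samples, with unique rownames (gene
#'   IDs) and colnames (sample IDs); all values finite.
#' @param labels Named character vector mapping each sample ID to `"case"`
#'   or `"control"`; every column of `values` must be labeled and each group
#'   must contain at least 2 samples.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, labels) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique rownames (gene IDs)")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique colnames (sample IDs)")
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  labels <- labels[colnames(values)]
  if (any(is.na(labels))) {
    stop("unlabeled samples: ",
         paste(colnames(values)[is.na(labels)], collapse = ", "))
  }
  if (!all(labels %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  if (sum(labels == "case") < 2L || sum(labels == "control") < 2L) {
    stop("each group needs at least 2 samples")
  }
  structure(list(values = values, labels = labels), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix genes=%d samples=%d (case=%d control=%d)>\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Two-sample t-test (Welch or pooled)
#'
#' Closed-form two-sided two-sample t-test. The Welch (unequal-variance)
#' form is the default, appropriate for unequal group sizes; the pooled
#' (Student) form is available behind `pooled = TRUE`. Degenerate inputs are
#' handled explicitly: two constant samples with equal value give `t = 0,
#' p = 1`; two constant samples with different values give `p = 0` with a
#' warning (infinite evidence under a zero-variance model).
#'
#' @param x,y Numeric vectors, each of length >= 2, finite.
#' @param pooled Use the pooled-variance Student form instead of Welch.
#' @return A list with elements `t`, `p` (two-sided) and `df`.
#' @export
t_test_two_sample <- function(x, y, pooled = FALSE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  nx <- length(x)
  ny <- length(y)
  vx <- stats::var(x)
  vy <- stats::var(y)
  mdiff <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (mdiff == 0) return(list(t = 0, p = 1, df = NA_real_))
    warning("both samples constant with unequal means: degenerate variance")
    return(list(t = sign(mdiff) * Inf, p = 0, df = NA_real_))
  }
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- mdiff / se
  list(t = tstat, p = 2 * pt(abs(tstat), df, lower.tail = FALSE), df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply by `m / rank`, enforce
#' monotonicity from the largest rank downward, clip at 1, and return in the
#' input order. Output is elementwise >= input.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be in [0, 1]")
  }
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
  adj
}

#' Call differentially expressed genes
#'
#' Runs a per-gene two-sample t-test (case vs control) across all genes,
#' adjusts the p-values jointly by Benjamini-Hochberg, and flags genes with
#' `fdr < alpha` (strict inequality). Zero-variance genes follow the
#' degenerate rules of [t_test_two_sample()] and never crash the scan.
#'
#' @param em An [expression_matrix()].
#' @param alpha FDR cutoff (default 0.05).
#' @param pooled Use the pooled t-test form (default Welch).
#' @return A `data.frame` with columns `gene_id`, `t`, `p`, `fdr`, `is_deg`,
#'   one row per gene in input order.
#' @export
call_degs <- function(em, alpha = 0.05, pooled = FALSE) {
  stopifnot(inherits(em, "expr_matrix"),
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  case <- em$values[, em$labels == "case", drop = FALSE]
  ctrl <- em$values[, em$labels == "control", drop = FALSE]
  nx <- ncol(case)
  ny <- ncol(ctrl)
  mx <- rowMeans(case)
  my <- rowMeans(ctrl)
  vx <- rowSums((case - mx)^2) / (nx - 1)
  vy <- rowSums((ctrl - my)^2) / (ny - 1)
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(se))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degen <- vx == 0 & vy == 0
  if (any(degen)) {
    eq <- degen & (mx == my)
    ne <- degen & (mx != my)
    tstat[eq] <- 0
    p[eq] <- 1
    if (any(ne)) {
      warning(sum(ne), " gene(s) constant in both groups with unequal means")
      tstat[ne] <- sign(mx[ne] - my[ne]) * Inf
      p[ne] <- 0
    }
  }
  fdr <- bh_adjust(p)
  data.frame(
    gene_id = rownames(em$values),
    t = tstat,
    p = p,
    fdr = fdr,
    is_deg = fdr < alpha,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Read an expression matrix and sample labels from TSV
#'
#' The expression file has gene IDs in column 1 and sample IDs in the header
#' row; the label file is a two-column TSV of `sample_id`, `group` with group
#' values `case`/`control`.
#'
#' @param expr_path Path to the expression TSV.
#' @param labels_path Path to the label TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(expr_path, labels_path) {
  dt <- data.table::fread(expr_path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(vals) <- as.character(dt[[1L]])
  lab <- data.table::fread(labels_path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  labels <- setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  expression_matrix(vals, labels)
}

#' Write a DEG table as TSV
#' @param deg A `data.frame` from [call_degs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  data.table::fwrite(deg, path, sep = "\t")
  invisible(path)
}
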