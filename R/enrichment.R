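## Evaluation analytics: per-system ROC AUC, top-N success rates under the
## scheme-dependent model-selection convention, positive/negative density
## separation, smoothed-density precision curves, and decoy-set summary
## tables.
##
## A labeled decoy table is a long data.frame with one row per model and
## columns: system_id, model_id, method, docking_score (oriented),
## composite, quality_docking, quality_af2. Under the docking scheme,
## models are ranked by docking_score and judged by the quality of the
## docking-generated variant; under the af2_composite scheme they are
## ranked by composite and judged by the rebuilt-model variant.

.schemeCols <- function(scheme = c("docking", "af2_composite")) {
    scheme <- match.arg(scheme)
    if (scheme == "docking")
        list(score = "docking_score", quality = "quality_docking")
    else
        list(score = "composite", quality = "quality_af2")
}

#' Rank-based ROC AUC for one system
#'
#' Area under the ROC curve computed by the Mann-Whitney statistic: the
#' probability that a random positive outscores a random negative, with
#' ties granted half credit. A system lacking positives or negatives
#' cannot be scored and yields NA (the "system excluded" signal) rather
#' than an error.
#'
#' @param pos numeric scores of the positive models.
#' @param neg numeric scores of the negative models.
#' @return AUC in [0, 1], or NA when either class is empty.
#' @examples
#' rocAuc(c(3, 4), c(1, 2)) # 1
#' rocAuc(1, 1)             # 0.5 by the tie convention
#' @export
rocAuc <- function(pos, neg) {
    nPos <- length(pos); nNeg <- length(neg)
    if (!nPos || !nNeg)
        return(NA_real_)
    r <- rank(c(pos, neg))
    (sum(r[seq_len(nPos)]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Success of a ranked list at depth N
#'
#' TRUE when any of the top-N entries of a ranked list is a positive. N
#' beyond the list length is evaluated at the full length.
#'
#' @param positive logical vector in rank order (TRUE = positive model).
#' @param n depth, >= 1.
#' @return logical scalar.
#' @export
successAtN <- function(positive, n) {
    if (n < 1) stop("n must be >= 1")
    any(positive[seq_len(min(n, length(positive)))])
}

.rankSystem <- function(sys, cols, floor) {
    ord <- order(-sys[[cols$score]])       # stable ties
    isPositive <- capriFactor(as.character(sys[[cols$quality]])) >= floor
    isPositive[ord]
}

#' Success curve over a collection of systems
#'
#' For each depth N = 1..maxN, the fraction of systems whose ranked list
#' holds at least one model of at least \code{floor} quality among the top
#' N. The ranking score and the model variant whose quality is judged are
#' both set by \code{scheme}: docking scores are judged on the
#' docking-generated models, composite rescoring on the rebuilt models.
#' Systems with no positives at all are retained (they simply never
#' succeed), so the curve also reflects outright docking failures.
#'
#' @param decoys labeled decoy table (see file header for columns).
#' @param scheme \code{"docking"} or \code{"af2_composite"}.
#' @param floor minimum CAPRI quality counting as success:
#'   \code{"Acceptable"} (default) or \code{"Medium"}.
#' @param maxN curve depth (default: largest per-system model count).
#' @return data.frame with columns \code{n} and \code{success} (fraction
#'   of systems), nondecreasing in \code{n}.
#' @export
successCurve <- function(decoys, scheme = c("docking", "af2_composite"),
                         floor = c("Acceptable", "Medium"), maxN = NULL) {
    cols <- .schemeCols(scheme)
    floor <- match.arg(floor)
    bySystem <- split(decoys, decoys$system_id)
    if (is.null(maxN))
        maxN <- max(vapply(bySystem, nrow, 1L))
    hit <- vapply(bySystem, function(sys) {
        pos <- .rankSystem(sys, cols, floor)
        vapply(seq_len(maxN), function(n) successAtN(pos, n), logical(1))
    }, logical(maxN))
    data.frame(n = seq_len(maxN),
               success = rowMeans(matrix(hit, nrow = maxN)))
}

#' Per-system ROC AUC table
#'
#' Computes [rocAuc()] for every system of a labeled decoy table under one
#' scheme. Systems with an empty class under that scheme get NA.
#'
#' @inheritParams successCurve
#' @return data.frame with columns \code{system_id} and \code{auc}.
#' @export
perSystemAUC <- function(decoys, scheme = c("docking", "af2_composite"),
                         floor = c("Acceptable", "Medium")) {
    cols <- .schemeCols(scheme)
    floor <- match.arg(floor)
    bySystem <- split(decoys, decoys$system_id)
    auc <- vapply(bySystem, function(sys) {
        pos <- capriFactor(as.character(sys[[cols$quality]])) >= floor
        rocAuc(sys[[cols$score]][pos], sys[[cols$score]][!pos])
    }, numeric(1))
    data.frame(system_id = names(bySystem), auc = unname(auc),
               stringsAsFactors = FALSE)
}

#' Median separation of positives and negatives in SD units
#'
#' Distance between the medians of the positive-score and negative-score
#' distributions, expressed in units of the pooled standard deviation of
#' all scores (or, alternatively, of the negatives only). Invariant under
#' a common affine transform of all scores.
#'
#' @param pos,neg numeric score vectors, both non-empty.
#' @param denominator \code{"pooled"} (default) or \code{"negatives"}.
#' @return dimensionless separation >= 0.
#' @export
separationSd <- function(pos, neg,
                         denominator = c("pooled", "negatives")) {
    denominator <- match.arg(denominator)
    if (!length(pos) || !length(neg))
        stop("both classes must be non-empty")
    s <- if (denominator == "pooled") stats::sd(c(pos, neg))
         else stats::sd(neg)
    if (!is.finite(s) || s == 0)
        stop("zero score spread: separation undefined")
    abs(stats::median(pos) - stats::median(neg)) / s
}

#' Smoothed-density precision curve
#'
#' Precision as a function of a sliding score threshold, computed from
#' Gaussian kernel density estimates of the two class score distributions
#' rather than raw counts, to avoid outlier bias. For threshold t,
#' \deqn{precision(t) = w_+ S_+(t) / (w_+ S_+(t) + w_- S_-(t))}
#' where S is the survival mass of the class density above t and w the
#' class count. The uncertainty band is the binomial standard error at the
#' effective number of models above t (fewer models, larger error).
#'
#' @param pos,neg numeric score vectors, n >= 5 each, not all equal.
#' @param nGrid number of threshold grid points (default 512); the grid
#'   spans the data range extended by 3 bandwidths on each side.
#' @param level band coverage (default 0.95).
#' @return data.frame with columns \code{threshold}, \code{precision},
#'   \code{lower}, \code{upper}, \code{nEffective}.
#' @export
precisionCurve <- function(pos, neg, nGrid = 512L, level = 0.95) {
    if (length(pos) < 5L || length(neg) < 5L)
        stop("need at least 5 scores per class")
    if (stats::sd(pos) == 0 || stats::sd(neg) == 0)
        stop("degenerate (all-equal) scores in one class")
    bwPos <- stats::bw.nrd0(pos)           # Silverman's rule
    bwNeg <- stats::bw.nrd0(neg)
    pad <- 3 * max(bwPos, bwNeg)
    lo <- min(pos, neg) - pad
    hi <- max(pos, neg) + pad
    dPos <- stats::density(pos, bw = bwPos, from = lo, to = hi, n = nGrid)
    dNeg <- stats::density(neg, bw = bwNeg, from = lo, to = hi, n = nGrid)
    dx <- dPos$x[2] - dPos$x[1]
    survPos <- rev(cumsum(rev(dPos$y))) * dx
    survNeg <- rev(cumsum(rev(dNeg$y))) * dx
    wPos <- length(pos); wNeg <- length(neg)
    num <- wPos * survPos
    den <- wPos * survPos + wNeg * survNeg
    precision <- ifelse(den > 0, num / den, NA_real_)
    nEff <- den
    se <- sqrt(pmax(precision * (1 - precision), 0) / pmax(nEff, 1))
    z <- stats::qnorm(1 - (1 - level) / 2)
    data.frame(threshold = dPos$x,
               precision = precision,
               lower = pmax(precision - z * se, 0),
               upper = pmin(precision + z * se, 1),
               nEffective = nEff)
}

#' Summarize labeled decoy sets per method and model variant
#'
#' Produces the standard composition summary of a decoy benchmark: per
#' docking method and model variant (docking-generated vs rebuilt), the
#' number of systems, models, positives (with percentage of models),
#' negatives, and the mean and SD of positives per system; plus a
#' cross-method total row per variant.
#'
#' @param decoys labeled decoy table (see [successCurve()]).
#' @return data.frame with columns \code{method}, \code{variant},
#'   \code{systems}, \code{models}, \code{positives},
#'   \code{positive_pct}, \code{negatives}, \code{ps_mean}, \code{ps_sd}.
#'   Percentages and P/S statistics are rounded to one decimal.
#' @export
summarizeDecoySet <- function(decoys) {
    variants <- c(docking = "quality_docking", af2 = "quality_af2")
    rows <- list()
    for (v in names(variants)) {
        qcol <- variants[[v]]
        for (m in c(unique(decoys$method), "All")) {
            d <- if (m == "All") decoys
                 else decoys[decoys$method == m, , drop = FALSE]
            if (!nrow(d)) next
            posBySys <- tapply(isPositive(d[[qcol]]), d$system_id, sum)
            nPos <- sum(posBySys)
            rows[[length(rows) + 1L]] <- data.frame(
                method = m, variant = v,
                systems = length(posBySys), models = nrow(d),
                positives = nPos,
                positive_pct = round(100 * nPos / nrow(d), 1),
                negatives = nrow(d) - nPos,
                ps_mean = round(mean(posBySys), 1),
                ps_sd = round(stats::sd(posBySys), 1),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Recompute decoy-set summary statistics from composition counts
#'
#' Given per-method composition counts of a decoy benchmark (systems,
#' models, positives), recomputes the derived summary statistics: the
#' positive percentage of models, the negative count, and the mean number
#' of positives per system, each rounded to one decimal as conventionally
#' reported; plus a per-set total row ("All").
#'
#' @param counts data.frame with columns \code{set}, \code{method},
#'   \code{systems}, \code{models}, \code{positives}.
#' @return the input with added columns \code{positive_pct},
#'   \code{negatives}, \code{ps_mean}, and appended "All" rows per set.
#' @seealso [referenceComposition()] for the bundled reference counts.
#' @export
compositionSummary <- function(counts) {
    need <- c("set", "method", "systems", "models", "positives")
    if (!all(need %in% names(counts)))
        stop("counts needs columns: ", paste(need, collapse = ", "))
    counts <- counts[, need]
    totals <- do.call(rbind, lapply(split(counts, counts$set), function(d)
        data.frame(set = d$set[1], method = "All",
                   systems = max(d$systems), models = sum(d$models),
                   positives = sum(d$positives),
                   stringsAsFactors = FALSE)))
    out <- rbind(counts, totals)
    out$positive_pct <- round(100 * out$positives / out$models, 1)
    out$negatives <- out$models - out$positives
    out$ps_mean <- round(out$positives / out$systems, 1)
    rownames(out) <- NULL
    out
}

#' Reference composition counts of the antibody-antigen decoy benchmark
#'
#' Published composition of the bound-backbone (231 systems) and
#' unbound-backbone (25 systems) antibody-antigen decoy benchmarks built
#' with ProPOSE, ZDOCK, PIPER and ClusPro: per method and set, the number
#' of systems and models and the number of positives (models of at least
#' acceptable CAPRI quality) for both the docking-generated and the
#' rebuilt model variants, together with the reported derived statistics
#' (percentages, negatives, positives-per-system mean and SD).
#'
#' @return data.frame, one row per (set, method, variant).
#' @export
referenceComposition <- function() {
    path <- system.file("extdata", "decoy_set_composition.csv",
                        package = "AbAgRescore", mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}
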