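## Per-system standardization of confidence metrics, the composite
## z-score used for reranking, docking-score orientation conventions and
## ranked-list construction.

#' Standardize an ensemble of scores (z-scores)
#'
#' Centers and scales a vector of scores from one ensemble of docked
#' models of a single system: mean 0, sample standard deviation
#' (denominator n - 1) 1. A constant ensemble maps to all zeros with a
#' warning rather than an error, so that pooling never fails on a
#' degenerate system.
#'
#' @param values numeric vector, length >= 2.
#' @param ddof degrees-of-freedom correction for the standard deviation
#'   (default 1, the sample SD).
#' @return numeric vector of standardized scores.
#' @examples
#' zscores(c(0.2, 0.4, 0.6)) # -1 0 1
#' @export
zscores <- function(values, ddof = 1) {
    values <- as.numeric(values)
    n <- length(values)
    if (n < 2L)
        stop("ensemble too small: need at least 2 models")
    if (anyNA(values) || any(!is.finite(values)))
        stop("scores must be finite")
    s <- stats::sd(values) * sqrt((n - 1) / (n - ddof))
    if (s == 0) {
        warning("constant ensemble: z-scores set to 0")
        return(rep(0, n))
    }
    (values - mean(values)) / s
}

#' Composite confidence score of an ensemble (sum of z-scores)
#'
#' For the docked-model ensemble of one system scored by one method,
#' standardizes the per-model pLDDT and pTM-score confidence metrics
#' within the ensemble and sums the two z-scores:
#' \deqn{composite = z_{pLDDT} + z_{pTMscore}}
#' The two terms are deliberately unweighted. pLDDT supplied on the 0-100
#' convention is normalized to 0-1 on ingest (standardization makes this
#' cosmetic). Ensembles smaller than 25 models trigger a warning: the
#' standardized scores then carry errors of the order of one composite
#' unit.
#'
#' @param records data.frame with columns \code{system_id},
#'   \code{model_id}, \code{method}, \code{plddt}, \code{ptmscore}; all
#'   rows must belong to one system and one method.
#' @return the input with added columns \code{z_plddt}, \code{z_ptmscore}
#'   and \code{composite}.
#' @seealso [rescoreTable()] to apply this per (system, method) group.
#' @export
compositeScores <- function(records) {
    need <- c("system_id", "model_id", "method", "plddt", "ptmscore")
    if (!all(need %in% names(records)))
        stop("records need columns: ", paste(need, collapse = ", "))
    if (length(unique(records$system_id)) > 1L)
        stop("mixed systems: standardize within one system at a time")
    if (length(unique(records$method)) > 1L)
        stop("mixed methods: standardize within one method at a time")
    n <- nrow(records)
    if (n < 25L)
        warning("ensemble of ", n, " models (< 25): standardized scores ",
                "may carry errors around one composite unit")
    plddt <- records$plddt
    if (any(plddt > 1)) plddt <- plddt / 100
    if (any(plddt < 0 | plddt > 1) ||
        any(records$ptmscore < 0 | records$ptmscore > 1))
        stop("confidence metrics must lie in [0, 1] after normalization")
    records$z_plddt <- zscores(plddt)
    records$z_ptmscore <- zscores(records$ptmscore)
    records$composite <- records$z_plddt + records$z_ptmscore
    records
}

#' Apply composite scoring across a whole confidence table
#'
#' Splits a confidence table by (system, method), applies
#' [compositeScores()] to each ensemble, and rebinds. Ensembles with fewer
#' than 2 models are dropped with a warning.
#'
#' @param records data.frame as in [compositeScores()], any number of
#'   systems and methods.
#' @param quiet suppress small-ensemble warnings (default TRUE; the
#'   per-ensemble warning is mostly useful interactively).
#' @return data.frame with z-score and composite columns added.
#' @export
rescoreTable <- function(records, quiet = TRUE) {
    grp <- interaction(records$system_id, records$method, drop = TRUE)
    parts <- split(records, grp)
    keep <- vapply(parts, nrow, 1L) >= 2L
    if (any(!keep))
        warning(sum(!keep), " ensemble(s) with < 2 models dropped")
    f <- if (quiet) function(p) suppressWarnings(compositeScores(p))
         else compositeScores
    out <- do.call(rbind, lapply(parts[keep], f))
    rownames(out) <- NULL
    out
}

#' Orient docking scores so that higher is always better
#'
#' Docking methods report scores under different conventions: lower
#' (more negative) energies are better for ProPOSE and PIPER, so their
#' sign is flipped; ZDOCK scores are already higher-is-better; ClusPro
#' models are scored by the size of their cluster, used as-is. Unknown
#' methods require an explicit \code{higherIsBetter}.
#'
#' @param raw numeric vector of method-native scores (for ClusPro, cluster
#'   sizes).
#' @param method a single method name: \code{"ProPOSE"}, \code{"ZDOCK"},
#'   \code{"PIPER"}, \code{"ClusPro"}, or anything else with
#'   \code{higherIsBetter} supplied.
#' @param higherIsBetter logical override for methods not built in.
#' @return numeric vector of oriented scores (higher = better). Ties keep
#'   the original input order when ranked with [rankModels()], matching
#'   the cluster-output convention.
#' @export
orientDockingScores <- function(raw, method, higherIsBetter = NULL) {
    flip <- c(ProPOSE = TRUE, PIPER = TRUE, ZDOCK = FALSE, ClusPro = FALSE)
    if (method %in% names(flip)) {
        if (flip[[method]]) -raw else raw
    } else if (!is.null(higherIsBetter)) {
        if (higherIsBetter) raw else -raw
    } else {
        stop("unknown method '", method,
             "': supply higherIsBetter explicitly")
    }
}

#' Rank models by an oriented score
#'
#' Sorts models by descending score with stable tie-breaking (ties keep
#' their original input order, the convention used for equal-size
#' clusters) and assigns ranks 1..n.
#'
#' @param modelId vector of model identifiers.
#' @param score numeric vector of oriented scores (higher = better); must
#'   be finite.
#' @param scheme label recorded on the output, e.g. \code{"docking"} or
#'   \code{"af2_composite"}.
#' @return data.frame with columns \code{rank}, \code{model_id},
#'   \code{score}, \code{scheme}.
#' @export
rankModels <- function(modelId, score, scheme = "docking") {
    if (length(modelId) != length(score))
        stop("modelId and score lengths differ")
    if (anyNA(score) || any(!is.finite(score)))
        stop("scores must be finite (no NA/NaN)")
    ord <- order(-score)          # order() is stable: ties keep input order
    data.frame(rank = seq_along(ord), model_id = modelId[ord],
               score = score[ord], scheme = scheme,
               stringsAsFactors = FALSE)
}

#' Pool standardized scores from several methods into one ranked list
#'
#' Merges per-method score tables for one system into a single ranked
#' list. Because raw docking scores are not comparable across methods,
#' every method's scores must already be standardized within its own
#' (system, method) ensemble; this is checked (mean 0, unit sample SD up
#' to numerical tolerance) and violated input is rejected.
#'
#' @param scoreTable data.frame with columns \code{method},
#'   \code{model_id}, \code{score} for a single system; \code{score}
#'   standardized within each method.
#' @param scheme label for the output ranked list.
#' @param tol tolerance on the standardization check (default 1e-6;
#'   constant all-zero ensembles are also accepted).
#' @return ranked-list data.frame as from [rankModels()], with a
#'   \code{method} column carried along.
#' @export
poolMethods <- function(scoreTable, scheme = "pooled", tol = 1e-6) {
    need <- c("method", "model_id", "score")
    if (!all(need %in% names(scoreTable)))
        stop("scoreTable needs columns: ", paste(need, collapse = ", "))
    for (m in unique(scoreTable$method)) {
        s <- scoreTable$score[scoreTable$method == m]
        if (length(s) < 2L) next
        ok <- abs(mean(s)) < tol &&
            (abs(stats::sd(s) - 1) < tol || all(s == 0))
        if (!ok)
            stop("scores of method '", m, "' are not standardized; ",
                 "apply zscores() within (system, method) before pooling")
    }
    ranked <- rankModels(seq_len(nrow(scoreTable)), scoreTable$score,
                         scheme)
    idx <- ranked$model_id
    data.frame(rank = ranked$rank,
               model_id = scoreTable$model_id[idx],
               method = scoreTable$method[idx],
               score = ranked$score, scheme = scheme,
               stringsAsFactors = FALSE)
}
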