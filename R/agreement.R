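#' Dice similarity coefficient between two binary masks
#'
#' DSC = 2|A n B| / (|A| + |B|). Two empty masks agree on absence and
#' score 1 (a message is emitted when this convention triggers).
#'
#' @param a,b \linkS4class{VoxelMask} or 0/1 arrays of identical shape.
#' @return numeric in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
    da <- if (is(a, "VoxelMask")) a@data else a
    db <- if (is(b, "VoxelMask")) b@data else b
    if (!all(dim(da) == dim(db)))
        stop("mask shapes differ", call. = FALSE)
    sa <- sum(da == 1L); sb <- sum(db == 1L)
    if (sa + sb == 0L) {
        message("both masks empty: Dice defined as 1 (agreement on absence)")
        return(1.0)
    }
    2 * sum(da == 1L & db == 1L) / (sa + sb)
}

#' Median absolute error between paired measurements
#'
#' The robust "MAE" used throughout: the median of |pred - truth|
#' (even-length median = mean of the middle two).
#'
#' @param pred,truth equal-length numeric vectors.
#' @return numeric(1).
#' @export
medianAbsError <- function(pred, truth) {
    if (length(pred) != length(truth))
        stop("pred and truth lengths differ", call. = FALSE)
    if (length(pred) == 0L) stop("empty input", call. = FALSE)
    stats::median(abs(pred - truth))
}

#' Gwet's AC1 chance-corrected agreement coefficient
#'
#' Observed agreement pa is the mean per-item pairwise rater agreement;
#' chance agreement uses prevalence-based category probabilities,
#' pe = (1/(K-1)) * sum_k pi_k (1 - pi_k) with pi_k the mean rater marginal
#' for category k; AC1 = (pa - pe) / (1 - pe). For two raters and two
#' categories this reduces to pe = 2 pi (1 - pi). Robust to prevalence
#' imbalance, unlike kappa.
#'
#' @param ratings items x raters matrix (or data.frame) of categorical
#'   labels; >= 2 raters and >= 1 item.
#' @param categories optional full category set (labels never observed
#'   still enter K).
#' @return an \linkS4class{AgreementResult}.
#' @export
gwetAC1 <- function(ratings, categories = NULL) {
    ratings <- as.matrix(ratings)
    n <- nrow(ratings); r <- ncol(ratings)
    if (r < 2L) stop("need >= 2 raters", call. = FALSE)
    if (n < 1L) stop("need >= 1 item", call. = FALSE)
    cats <- if (is.null(categories)) sort(unique(as.vector(ratings)))
            else as.character(categories)
    K <- length(cats)
    counts <- vapply(cats, function(k) rowSums(ratings == k),
                     numeric(n))
    counts <- matrix(counts, nrow = n)     # items x categories
    pa <- mean(rowSums(counts * (counts - 1)) / (r * (r - 1)))
    piK <- colMeans(counts / r)
    if (K < 2L) {
        # single observed category: perfect agreement by construction
        return(new("AgreementResult", pa = pa, pe = NA_real_, ac1 = 1.0,
                   nItems = as.integer(n), categories = cats))
    }
    pe <- sum(piK * (1 - piK)) / (K - 1)
    ac1 <- if (pe < 1) (pa - pe) / (1 - pe) else 1.0
    new("AgreementResult", pa = pa, pe = pe, ac1 = ac1,
        nItems = as.integer(n), categories = cats)
}

#' Read a ratings table from CSV
#'
#' Expects columns \code{item_id}, \code{rater_id}, \code{label}; returns
#' the items x raters matrix for \code{\link{gwetAC1}}.
#'
#' @param path CSV path.
#' @return character matrix items x raters.
#' @export
readRatingsCSV <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("item_id", "rater_id", "label")
    if (!all(need %in% names(df)))
        stop("ratings CSV needs columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    items <- sort(unique(df$item_id))
    raters <- sort(unique(df$rater_id))
    m <- matrix(NA_character_, length(items), length(raters),
                dimnames = list(items, raters))
    m[cbind(match(df$item_id, items), match(df$rater_id, raters))] <- df$label
    if (any(is.na(m)))
        stop("incomplete ratings table: every item needs every rater",
             call. = FALSE)
    m
}
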