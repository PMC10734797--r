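# One-vs-rest evaluation of the proxy against clinician-recorded EDSS:
# per-class confusion counts, sensitivity/specificity/PPV/NPV/accuracy/
# Cohen's kappa/F1, macro-averaged F1, and MSE/MAE on the step scale.

#' One-vs-rest confusion counts for a target class
#'
#' @param truth,pred equal-length vectors of class labels from one scheme.
#' @param target the class treated as positive.
#' @return list with integer `tp`, `tn`, `fp`, `fn` (summing to `length(truth)`).
#' @export
confusion_counts <- function(truth, pred, target) {
  if (length(truth) != length(pred))
    stop("truth and pred must have the same length (",
         length(truth), " vs ", length(pred), ")")
  if (length(truth) == 0L) stop("empty label vectors")
  t_pos <- truth == target
  p_pos <- pred == target
  list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
       fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
}

#' Performance metrics from a 2x2 confusion table
#'
#' Computes sensitivity (recall, TP/(TP+FN)), specificity (TN/(FP+TN)),
#' positive and negative predictive value (TP/(TP+FP), TN/(FN+TN)), accuracy
#' ((TP+TN)/N), Cohen's kappa on the 2x2 one-vs-rest table
#' (kappa = (p_o - p_e)/(1 - p_e) with p_o = (TP+TN)/N and
#' p_e = ((TP+FP)(TP+FN) + (TN+FN)(TN+FP))/N^2), and the F1 score (harmonic
#' mean of precision and recall). Conventions for degenerate tables: a
#' proportion with a zero denominator is 0, F1 is 0 when precision + recall
#' is 0, and kappa is 0 when p_e = 1.
#'
#' @param tp,tn,fp,fn non-negative counts; alternatively pass the list
#'   returned by [confusion_counts()] as `tp`.
#' @return named list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, `kappa`, `f1` (unrounded).
#' @export
class_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    c0 <- tp; tp <- c0$tp; tn <- c0$tn; fp <- c0$fp; fn <- c0$fn
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion table")
  ratio <- function(num, den) if (den == 0) 0 else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, fp + tn)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, fn + tn)
  acc <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (p_e == 1) 0 else (acc - p_e) / (1 - p_e)
  f1 <- if (ppv + sens == 0) 0 else 2 * ppv * sens / (ppv + sens)
  list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       accuracy = acc, kappa = kappa, f1 = f1)
}

#' Macro-averaged F1 score
#'
#' Arithmetic mean of the (unrounded) per-class F1 scores.
#'
#' @param f1s numeric vector of per-class F1 values.
#' @return single numeric.
#' @export
macro_f1 <- function(f1s) {
  if (length(f1s) == 0L) stop("no per-class F1 values supplied")
  mean(f1s)
}

#' Mean squared and mean absolute prediction error
#'
#' @param truth_numeric,pred_numeric equal-length numeric vectors on the step
#'   scale (the "8plus" group encoded as 8, see [class_numeric()]).
#' @return list with `mse` and `mae`.
#' @export
error_summary <- function(truth_numeric, pred_numeric) {
  if (length(truth_numeric) != length(pred_numeric))
    stop("truth and pred must have the same length")
  if (length(truth_numeric) == 0L) stop("empty score vectors")
  d <- truth_numeric - pred_numeric
  list(mse = mean(d^2), mae = mean(abs(d)))
}

#' Evaluate proxy steps against reference EDSS scores
#'
#' Rescales the reference scores to the proxy grid, optionally applies the
#' 0-to-1 imputation to the proxy steps, classifies both sides under the
#' chosen scheme, and computes per-class one-vs-rest counts and metrics for
#' every label of the scheme, the macro F1, and the MSE/MAE on the numeric
#' step encoding (independent of the scheme, with values above 8 collapsed
#' into the "8plus" group).
#'
#' @param true_edss numeric vector of reference EDSS values (half-point grid).
#' @param pedss integer vector of proxy steps 0-9, paired with `true_edss`.
#' @param scheme classifier scheme, see [scheme_labels()].
#' @param impute apply the 0 -> 1 proxy imputation (default TRUE, as in the
#'   validation pathway).
#' @return object of class `pedss_evaluation`: list with `scheme`, `n`,
#'   `table` (one row per class: counts and metrics), `macro_f1`, `mse`,
#'   `mae`.
#' @export
pedss_evaluate <- function(true_edss, pedss,
                           scheme = c("eightfold", "threefold", "binary"),
                           impute = TRUE) {
  scheme <- match.arg(scheme)
  if (length(true_edss) != length(pedss))
    stop("true_edss and pedss must be paired vectors of the same length")
  if (length(true_edss) == 0L) stop("no paired observations")
  truth_val <- rescale_edss(true_edss)
  pred_val <- if (impute) impute_pedss(pedss) else as.integer(pedss)
  if (any(pred_val < 1))
    stop("proxy step 0 present with impute = FALSE; classes are defined on 1..9")
  truth_lab <- edss_class(truth_val, scheme)
  pred_lab <- edss_class(pred_val, scheme)
  labels <- scheme_labels(scheme)
  rows <- lapply(labels, function(lb) {
    cc <- confusion_counts(truth_lab, pred_lab, lb)
    m <- class_metrics(cc)
    data.frame(class = lb, tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
               kappa = m$kappa, f1 = m$f1, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  err <- error_summary(class_numeric(edss_class(truth_val, "eightfold")),
                       class_numeric(edss_class(pmin(pred_val, 8L), "eightfold")))
  structure(list(scheme = scheme, n = length(true_edss), table = tab,
                 macro_f1 = macro_f1(tab$f1), mse = err$mse, mae = err$mae),
            class = "pedss_evaluation")
}

#' @export
print.pedss_evaluation <- function(x, digits = 2, ...) {
  cat(sprintf("pEDSS evaluation, %s classifier, n = %d paired observations\n",
              x$scheme, x$n))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1)) &
    !(names(tab) %in% c("tp", "tn", "fp", "fn"))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("macro F1 = %.*f   MSE = %.*f   MAE = %.*f\n",
              digits, x$macro_f1, digits, x$mse, digits, x$mae))
  invisible(x)
}

#' @export
summary.pedss_evaluation <- function(object, ...) print(object, ...)

#' Published validation confusion counts
#'
#' The one-vs-rest confusion counts (TP, TN, FP, FN over 100 paired index
#' measurements) reported by the validation study of this algorithm against
#' clinician-recorded EDSS from a specialist MS center, for all 13 classes of
#' the three classifier schemes. Feeding these counts through
#' [class_metrics()] and [macro_f1()] reproduces the study's published
#' per-class metrics and macro F1 scores.
#'
#' @return data.frame with columns `scheme`, `class`, `tp`, `tn`, `fp`, `fn`.
#' @export
validation_counts <- function() {
  data.frame(
    scheme = c(rep("eightfold", 8), rep("threefold", 3), rep("binary", 2)),
    class = c(as.character(1:7), "8plus", "1-3", "4-5", "6plus", "lt6", "ge6"),
    tp = c(13, 4, 8, 1, 1, 1, 4, 0, 58, 8, 11, 81, 11),
    tn = c(53, 75, 63, 83, 83, 90, 88, 97, 24, 72, 81, 11, 81),
    fp = c(29, 2, 10, 6, 13, 1, 5, 2, 8, 13, 2, 6, 2),
    fn = c(5, 19, 19, 10, 3, 8, 3, 1, 10, 7, 6, 2, 6),
    stringsAsFactors = FALSE
  )
}
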