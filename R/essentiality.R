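# In silico single-gene deletion screening. Deleting a gene disables every
# reaction whose GPR evaluates false without it (an isozyme OR keeps the
# reaction open); the knockout growth rate is recomputed by FBA or MOMA and
# compared to wild type. Calls are compared against an experimental
# essentiality truth table through ortholog mapping, yielding the standard
# confusion statistics.

#' Default essentiality cutoff on the growth ratio
#'
#' A knockout is called essential when its growth ratio mu_KO/mu_WT falls
#' below this fraction.
#' @export
LK_ESSENTIALITY_CUTOFF <- 0.01

#' Single-gene deletion screen
#'
#' @param model a `metabolic_model`.
#' @param med optional [medium()].
#' @param method `"fba"` (knockout re-optimizes growth) or `"moma"`
#'   (minimal flux adjustment from the wild-type state).
#' @param genes genes to screen (default: all model genes).
#' @param cutoff essentiality cutoff on the growth ratio.
#' @return an object of class `essentiality_report`: data.frame with columns
#'   `gene`, `growth_rate`, `growth_ratio`, `essential`, `n_disabled`
#'   (reactions shut by the deletion) and `method`; attribute `mu_wt`.
#' @export
single_gene_deletion <- function(model, med = NULL, method = c("fba", "moma"),
                                 genes = model$genes,
                                 cutoff = LK_ESSENTIALITY_CUTOFF) {
  method <- match.arg(method)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    warning("ignoring unknown genes: ", paste(unknown, collapse = ", "))
    genes <- intersect(genes, model$genes)
  }
  model <- apply_medium(model, med)
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective <= LK_FLUX_TOL)
    stop("wild type is non-viable under this medium (status ", wt$status,
         ", mu = ", if (wt$status == "optimal") wt$objective else NA, ")")
  mu_wt <- wt$objective
  trees <- lapply(model$reactions$gpr, gpr_parse)
  gene_rxns <- lapply(trees, gpr_genes)
  rows <- lapply(genes, function(g) {
    affected <- which(vapply(seq_along(trees), function(i) {
      g %in% gene_rxns[[i]] && !gpr_eval(trees[[i]], g)
    }, logical(1)))
    if (length(affected) == 0L) {
      mu_ko <- mu_wt
    } else {
      m2 <- model
      m2$reactions$lb[affected] <- 0
      m2$reactions$ub[affected] <- 0
      if (method == "fba") {
        s <- fba(m2)
        mu_ko <- if (s$status == "optimal") s$objective else 0
      } else {
        s <- moma(m2, wt)
        mu_ko <- if (s$status == "optimal") s$objective else 0
      }
    }
    ratio <- max(mu_ko, 0) / mu_wt
    data.frame(gene = g, growth_rate = mu_ko, growth_ratio = ratio,
               essential = ratio < cutoff, n_disabled = length(affected),
               method = method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, mu_wt = mu_wt, cutoff = cutoff,
            class = c("essentiality_report", "data.frame"))
}

#' Confusion statistics for essentiality predictions
#'
#' Compares in silico essentiality calls with an experimental truth table
#' through an ortholog map. Only genes with at least one mapped ortholog
#' enter the statistics; a gene mapped to several reference orthologs is
#' taken as experimentally essential only if all of them are essential
#' (conservative rule for duplicated reference genomes). The Matthews
#' correlation coefficient uses the standard square-rooted denominator.
#'
#' @param calls an `essentiality_report` (or data.frame with `gene` and
#'   `essential`).
#' @param truth named logical vector: reference gene id -> essential.
#' @param orthologs optional data.frame with columns `gene` and `reference`
#'   (one row per mapping; duplicates encode multi-orthology). `NULL` means
#'   identity mapping.
#' @return an object of class `confusion_stats`: list with counts `tp`,
#'   `fp`, `tn`, `fn`, the derived `accuracy`, `sensitivity`, `specificity`,
#'   `mcc`, `f1`, plus `n_compared` and `n_unmapped`.
#' @export
confusion_statistics <- function(calls, truth, orthologs = NULL) {
  pred <- stats::setNames(calls$essential, calls$gene)
  if (is.null(orthologs))
    orthologs <- data.frame(gene = names(truth), reference = names(truth))
  orthologs <- orthologs[orthologs$gene %in% names(pred) &
                         orthologs$reference %in% names(truth), , drop = FALSE]
  mapped <- unique(orthologs$gene)
  n_unmapped <- sum(!names(pred) %in% mapped)
  if (length(mapped) == 0L)
    stop("no genes could be compared: empty prediction/truth overlap")
  true_ess <- vapply(mapped, function(g) {
    refs <- orthologs$reference[orthologs$gene == g]
    all(truth[refs])
  }, logical(1))
  pred_ess <- pred[mapped]
  tp <- sum(pred_ess & true_ess)
  fp <- sum(pred_ess & !true_ess)
  tn <- sum(!pred_ess & !true_ess)
  fn <- sum(!pred_ess & true_ess)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  acc <- (tp + tn) / (tp + fp + tn + fn)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 mcc = mcc, f1 = f1,
                 n_compared = length(mapped), n_unmapped = n_unmapped),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("Confusion: TP=%d FP=%d TN=%d FN=%d (n=%d, unmapped=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_compared, x$n_unmapped))
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f  MCC %.3f  F1 %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$mcc, x$f1))
  invisible(x)
}

#' Standard media presets for essentiality screening
#'
#' Builds the conventional screening media on top of a model's exchange
#' inventory: a rich medium opening every organic uptake (amino acids,
#' nucleotides, carbohydrates — whatever the model offers), and minimal
#' media opening one carbon source plus the nitrogen source and trace
#' components. All presets are aerobic (O2 uptake 1000 mmol/gdw/h).
#' Components whose exchange reaction is absent are skipped with a warning.
#'
#' @param model a `metabolic_model`.
#' @param carbon named numeric vector of carbon-source exchanges and uptake
#'   rates: one minimal medium is built per entry.
#' @param nitrogen exchange id of the nitrogen source (uptake 1000).
#' @param trace character vector of freely available exchanges (water,
#'   protons, CO2, O2 are typical).
#' @param rich_extra additional exchanges opened only in the rich medium.
#' @return named list of [medium()] objects: `ypd_rich` plus one
#'   `minimal_<source>` per carbon entry.
#' @export
media_presets <- function(model, carbon, nitrogen, trace,
                          rich_extra = character()) {
  ex <- exchange_reactions(model)
  keep <- function(ids) {
    absent <- setdiff(ids, ex)
    if (length(absent))
      warning("skipping absent exchanges: ", paste(absent, collapse = ", "))
    intersect(ids, ex)
  }
  trace <- keep(trace)
  nitrogen <- keep(nitrogen)
  base <- stats::setNames(rep(LK_BIG_BOUND, length(trace) + length(nitrogen)),
                          c(trace, nitrogen))
  carbon <- carbon[names(carbon) %in% keep(names(carbon))]
  rich_up <- base
  rich_up[names(carbon)] <- carbon
  for (rid in keep(rich_extra)) rich_up[rid] <- LK_BIG_BOUND
  out <- list(ypd_rich = medium("ypd_rich", rich_up))
  for (k in seq_along(carbon)) {
    nm <- paste0("minimal_", sub("^EX_", "", names(carbon)[k]))
    up <- base
    up[names(carbon)[k]] <- carbon[[k]]
    out[[nm]] <- medium(nm, up)
  }
  out
}
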