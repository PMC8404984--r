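#' Pipeline configuration
#'
#' Defaults follow the method's selected operating point: solid-harmonic
#' order 6 with SNR-mask thresholds of 20 for both the minimax and fitting
#' steps, and a relative residual-change stopping tolerance of 0.01%.
#'
#' @param order solid-harmonic fit order.
#' @param minimax_snr SNR threshold of the minimax mask.
#' @param fit_snr SNR threshold of the fit mask.
#' @param tol variable-exchange stopping tolerance (relative residual
#'   change).
#' @param max_iter maximum variable-exchange iterations.
#' @param restarts minimax random restarts.
#' @param seed seed for the minimax restarts.
#' @param eps_combine relative magnitude floor in [combine_fitted()].
#' @param mask_erosions erosions applied to the evaluation mask.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(order = 6, minimax_snr = 20, fit_snr = 20,
                            tol = 1e-4, max_iter = 100, restarts = 8,
                            seed = 1, eps_combine = 1e-6,
                            mask_erosions = 1) {
  structure(list(order = order, minimax_snr = minimax_snr,
                 fit_snr = fit_snr, tol = tol, max_iter = max_iter,
                 restarts = restarts, seed = seed,
                 eps_combine = eps_combine, mask_erosions = mask_erosions),
            class = "pipeline_config")
}

#' Run the full fitted-SVD combination pipeline
#'
#' Executes estimation through evaluation in order: voxel-wise SVD of the
#' prescan, SNR masks, minimax reference weights, common-phase removal,
#' variable-exchange harmonic fitting, evaluation of the fit on the target
#' geometry, matched-filter combination of the target, the voxel-wise SVD
#' reference combination, and the quality/singularity report.
#'
#' @param prescan multi-image [coil_image_set()] used for estimation.
#' @param target [coil_image_set()] to combine (multi-volume for a
#'   meaningful voxel-wise SVD reference).
#' @param config a [pipeline_config()].
#' @param brain_mask optional logical vector over target voxels restricting
#'   evaluation (e.g. the phantom support); defaults to the evaluation mask
#'   derived from the target's sum-of-squares magnitude.
#' @return object of class `pipeline_result` with all intermediate stages
#'   (`estimate`, `snr`, `minimax_mask`, `fit_mask`, `ref_weights`,
#'   `aligned`, `fit`, `fitted_target`, `combined`, `reference`,
#'   `eval_mask`, `report`).
#' @export
run_pipeline <- function(prescan, target, config = pipeline_config(),
                         brain_mask = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  est <- stage("voxelwise_svd", voxelwise_svd(prescan))
  snr <- stage("snr_map", snr_map(est))
  mm_mask <- stage("minimax_mask",
                   snr_threshold_mask(snr, config$minimax_snr, "minimax"))
  fit_mask <- stage("fit_mask",
                    snr_threshold_mask(snr, config$fit_snr, "fit"))
  w <- stage("solve_minimax",
             solve_minimax(est, mm_mask, restarts = config$restarts,
                           seed = config$seed))
  aligned <- stage("remove_common_phase", remove_common_phase(est, w))
  fit <- stage("fit_variable_exchange",
               fit_variable_exchange(aligned, est$lambda1, fit_mask,
                                     order = config$order, tol = config$tol,
                                     max_iter = config$max_iter))
  fitted_target <- stage("evaluate_fit", evaluate_fit(fit, target$geometry))
  combined <- stage("combine_fitted",
                    combine_fitted(target, fitted_target,
                                   eps = config$eps_combine))
  reference <- stage("combine_vsvd", combine_vsvd(target))

  sos <- sqrt(rowSums(Mod(target$data[, , 1, drop = FALSE])^2))
  eval_mask <- stage("make_eval_mask",
                     make_eval_mask(sos, target$geometry,
                                    erosions = config$mask_erosions))
  if (!is.null(brain_mask)) eval_mask <- eval_mask & brain_mask
  report <- stage("quality_ratio",
                  quality_ratio(combined, reference, eval_mask))
  sing <- stage("count_singularities",
                count_singularities(Arg(combined$values[, 1]),
                                    mask = eval_mask,
                                    geometry = target$geometry))
  structure(list(estimate = est, snr = snr, minimax_mask = mm_mask,
                 fit_mask = fit_mask, ref_weights = w, aligned = aligned,
                 fit = fit, fitted_target = fitted_target,
                 combined = combined, reference = reference,
                 eval_mask = eval_mask, report = report,
                 singularities = sing, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (order ", x$config$order, ", thresholds ",
      x$config$minimax_snr, "/", x$config$fit_snr, ")\n", sep = "")
  print(x$report)
  cat("singularities in combined phase:", x$singularities$total, "\n")
  invisible(x)
}

#' Hyperparameter sweep over order and mask thresholds
#'
#' Full-factorial evaluation of the pipeline over grids of solid-harmonic
#' orders and SNR-mask thresholds, reporting the mean quality ratio and its
#' coefficient of variation per cell — the surface used to select the
#' operating point. The voxel-wise SVD estimate and the reference
#' combination are computed once and shared across cells. Cells whose mask
#' is empty are recorded as missing rather than failing the sweep.
#'
#' @inheritParams run_pipeline
#' @param orders integer vector of fit orders.
#' @param minimax_thresholds,fit_thresholds numeric threshold grids
#'   (defaults: nine equally spaced values from 5 to 45).
#' @return a data.frame with columns `order`, `minimax_thr`, `fit_thr`,
#'   `mean_q`, `cv`, `singularities`, `n_fit_voxels`, `converged`.
#' @export
parameter_sweep <- function(prescan, target, orders = 1:10,
                            minimax_thresholds = seq(5, 45, length.out = 9),
                            fit_thresholds = seq(5, 45, length.out = 9),
                            config = pipeline_config(),
                            brain_mask = NULL) {
  stopifnot(length(orders) > 0, length(minimax_thresholds) > 0,
            length(fit_thresholds) > 0)
  est <- voxelwise_svd(prescan)
  snr <- snr_map(est)
  reference <- combine_vsvd(target)
  sos <- sqrt(rowSums(Mod(target$data[, , 1, drop = FALSE])^2))
  eval_mask <- make_eval_mask(sos, target$geometry,
                              erosions = config$mask_erosions)
  if (!is.null(brain_mask)) eval_mask <- eval_mask & brain_mask

  grid <- expand.grid(order = orders, minimax_thr = minimax_thresholds,
                      fit_thr = fit_thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cell <- grid[g, ]
    out <- data.frame(order = cell$order, minimax_thr = cell$minimax_thr,
                      fit_thr = cell$fit_thr, mean_q = NA_real_,
                      cv = NA_real_, singularities = NA_integer_,
                      n_fit_voxels = NA_integer_, converged = NA)
    ok <- tryCatch({
      mm_mask <- snr_threshold_mask(snr, cell$minimax_thr, "minimax")
      fit_mask <- snr_threshold_mask(snr, cell$fit_thr, "fit")
      w <- solve_minimax(est, mm_mask, restarts = config$restarts,
                         seed = config$seed)
      aligned <- remove_common_phase(est, w)
      fit <- fit_variable_exchange(aligned, est$lambda1, fit_mask,
                                   order = cell$order, tol = config$tol,
                                   max_iter = config$max_iter)
      fitted_target <- evaluate_fit(fit, target$geometry)
      combined <- combine_fitted(target, fitted_target,
                                 eps = config$eps_combine)
      rep <- quality_ratio(combined, reference, eval_mask)
      sing <- count_singularities(Arg(combined$values[, 1]),
                                  mask = eval_mask,
                                  geometry = target$geometry)
      out$mean_q <- rep$mean
      out$cv <- rep$cv
      out$singularities <- sing$total
      out$n_fit_voxels <- length(fit$voxels)
      out$converged <- fit$converged
      TRUE
    }, error = function(e) FALSE)
    out
  })
  do.call(rbind, rows)
}
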