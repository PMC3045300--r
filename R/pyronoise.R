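#' Remove pyrosequencing noise by EM clustering of flowgrams
#'
#' Fits an exponential mixture model to the filtered flowgrams: each mixture
#' component is a candidate true sequence (restricted to the perfect
#' flowgrams obtained by rounding the observed flowgrams to integers, so every
#' denoised read maps back to an observed one), reads are distributed around
#' components as `exp(-d'/sigma_p)` in the flowgram distance `d'`, and the
#' component set, sequences and weights are estimated by
#' expectation-maximization. The EM is initialised from a complete-linkage
#' clustering of the pairwise flowgram distances cut at `cut_p`.
#'
#' @param flowgrams list of filtered [flowgram] objects, all with the same
#'   flow count.
#' @param model an [intensity_model]; defaults to [default_intensity_model()].
#' @param sigma_p cluster scale of the exponential kernel (default 1/60).
#' @param cut_p complete-linkage initialisation cut-off (default 0.01).
#' @param max_iter,tol convergence control: stop when the largest
#'   responsibility change drops below `tol`.
#' @return an object of class `"pyronoise"` with elements
#'   \describe{
#'     \item{components}{data frame `id`, `sequence`, `abundance` (mapped
#'       read counts), `tau` (mixture weight); zero-abundance components are
#'       dropped.}
#'     \item{runs}{list of the components' perfect flowgrams.}
#'     \item{mapping}{data frame `read_id`, `component` assigning every read
#'       to its maximum-responsibility component.}
#'     \item{loglik}{observed-data log-likelihood trace (non-decreasing).}
#'     \item{converged}{logical.}
#'   }
#' @export
pyronoise <- function(flowgrams, model = default_intensity_model(),
                      sigma_p = 1 / 60, cut_p = 0.01, max_iter = 1000,
                      tol = 1e-6) {
  if (length(flowgrams) < 1) stop("need at least one flowgram")
  M <- length(flowgrams[[1]]$values)
  if (!all(vapply(flowgrams, function(f) length(f$values), integer(1)) == M)) {
    stop("all flowgrams must have the same flow count")
  }
  flow_order <- flowgrams[[1]]$flow_order
  N <- length(flowgrams)
  V <- t(vapply(flowgrams, `[[`, numeric(M), "values"))
  dm <- normalized_dist_table(model)
  bins <- matrix(bin_index(V, model$bin_width, nrow(dm)) - 1L, N, M)

  R <- matrix(pmax(0L, as.integer(round(V))), N, M)
  key <- apply(R, 1, paste, collapse = ",")
  first <- !duplicated(key)
  cand_runs <- R[first, , drop = FALSE]
  cand_key <- key[first]
  counts <- as.integer(table(key)[cand_key])
  cand_seq <- apply(cand_runs, 1, flows_to_sequence, flow_order = flow_order)
  ord <- order(-counts, cand_seq)
  cand_runs <- cand_runs[ord, , drop = FALSE]
  cand_seq <- cand_seq[ord]
  read_cand <- match(key, cand_key[ord])

  D_full <- flow_dist_mat(bins, cand_runs, dm)
  Dsel <- D_full[, read_cand, drop = FALSE]
  init <- init_complete_linkage((Dsel + t(Dsel)) / 2, cut_p)
  fit <- run_em(D_full, init, sigma_p, weights = NULL, max_iter = max_iter,
                tol = tol)

  # collapse EM components onto their candidate centres and drop empty ones
  read_centre <- fit$centre[fit$mapping]
  used <- sort(unique(read_centre))
  abundance <- as.integer(table(factor(read_centre, levels = used)))
  tau_by_centre <- vapply(used, function(k) sum(fit$tau[fit$centre == k]),
                          numeric(1))
  ids <- sprintf("seq_%03d", seq_along(used))
  comp_of_read <- match(read_centre, used)
  structure(
    list(
      components = data.frame(id = ids, sequence = cand_seq[used],
                              abundance = abundance, tau = tau_by_centre,
                              stringsAsFactors = FALSE),
      runs = lapply(used, function(k) cand_runs[k, ]),
      mapping = data.frame(
        read_id = vapply(flowgrams, `[[`, character(1), "id"),
        component = ids[comp_of_read], stringsAsFactors = FALSE),
      loglik = fit$loglik, converged = fit$converged,
      iterations = fit$iterations, sigma_p = sigma_p, cut_p = cut_p,
      n_reads = N, n_flows = M, flow_order = flow_order
    ),
    class = "pyronoise"
  )
}

#' @export
print.pyronoise <- function(x, ...) {
  cat("Flowgram EM denoising (", x$n_reads, " reads, ", x$n_flows,
      " flows)\n", sep = "")
  cat("  components: ", nrow(x$components), "  sigma_p = ",
      format(x$sigma_p, digits = 4), "  cut_p = ", x$cut_p, "\n", sep = "")
  cat("  ", if (x$converged) "converged" else "NOT converged", " in ",
      x$iterations, " iterations, log-likelihood ",
      format(x$loglik[length(x$loglik)], digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary pyronoise
summary.pyronoise <- function(object, ...) {
  print(object)
  ord <- order(-object$components$abundance)
  print(head(object$components[ord, c("id", "abundance", "tau")], 10),
        row.names = FALSE)
  invisible(object)
}

#' @export
#' @method logLik pyronoise
logLik.pyronoise <- function(object, ...) {
  structure(object$loglik[length(object$loglik)],
            df = 2 * nrow(object$components), class = "logLik")
}

#' Denoised sequences of a fit, as a weighted-sequence data frame
#'
#' @param fit a `"pyronoise"` or `"seqnoise"` object.
#' @return data frame `id`, `seq`, `weight` (suitable for [seqnoise()] or
#'   [perseus()]).
#' @export
denoised_sequences <- function(fit) {
  comp <- fit$components
  data.frame(id = comp$id, seq = comp$sequence,
             weight = if ("frequency" %in% names(comp)) comp$frequency
                      else comp$abundance,
             stringsAsFactors = FALSE)
}
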