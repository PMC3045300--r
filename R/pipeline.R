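#' Pipeline configuration
#'
#' All tunable parameters of the denoising pipeline in one place, with the
#' standard published defaults: `sigma_p = 1/60`, `cut_p = 0.01` for the
#' flowgram stage; `sigma_s = 0.033` (GS FLX; 0.04 and 0.1 are the Titanium
#' presets), `cut_s = 0.08` for the sequence stage; gap penalties 15.0 /
#' 4.0; chimera classifier `alpha = -7.5`, `beta = 0.5` with distance gate
#' 0.15; flow truncation 360 (FLX) / 720 (Titanium) and base truncation 220 /
#' 400.
#'
#' @param platform `"FLX"` or `"TITANIUM"`.
#' @param sigma_p,cut_p flowgram-stage EM scale and initialisation cut-off.
#' @param sigma_s,cut_s sequence-stage EM scale and cut-off; `sigma_s`
#'   defaults by platform.
#' @param gap,hgap standard and homopolymer gap penalties.
#' @param alpha,beta logistic chimera classifier parameters.
#' @param dist_threshold chimera candidate distance gate.
#' @param truncate_flows,truncate_bases truncation points; platform defaults
#'   when `NULL`.
#' @param primer,tag read-filter primer (IUPAC) and tag.
#' @param intensity_model an [intensity_model]; the parametric default when
#'   `NULL`.
#' @param transition_probs 4x4 PCR substitution matrix.
#' @param seed seed recorded for provenance.
#' @param max_iter,tol EM convergence control.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(platform = c("FLX", "TITANIUM"),
                            sigma_p = 1 / 60, cut_p = 0.01, sigma_s = NULL,
                            cut_s = 0.08, gap = 15.0, hgap = 4.0,
                            alpha = -7.5, beta = 0.5, dist_threshold = 0.15,
                            truncate_flows = NULL, truncate_bases = NULL,
                            primer = "", tag = "", intensity_model = NULL,
                            transition_probs = pcr_transition_default(),
                            seed = 1L, max_iter = 1000, tol = 1e-6) {
  platform <- match.arg(platform)
  flx <- platform == "FLX"
  cfg <- list(
    platform = platform, sigma_p = sigma_p, cut_p = cut_p,
    sigma_s = if (is.null(sigma_s)) (if (flx) 0.033 else 0.04) else sigma_s,
    cut_s = cut_s, gap = gap, hgap = hgap, alpha = alpha, beta = beta,
    dist_threshold = dist_threshold,
    truncate_flows = if (is.null(truncate_flows)) (if (flx) 360L else 720L)
                     else as.integer(truncate_flows),
    truncate_bases = if (is.null(truncate_bases)) (if (flx) 220L else 400L)
                     else as.integer(truncate_bases),
    primer = primer, tag = tag, intensity_model = intensity_model,
    transition_probs = transition_probs, seed = as.integer(seed),
    max_iter = max_iter, tol = tol
  )
  stopifnot(cfg$sigma_p > 0, cfg$sigma_s > 0, cfg$cut_p >= 0, cfg$cut_s >= 0,
            cfg$gap > 0, cfg$hgap > 0, cfg$dist_threshold > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Arguments passed
#' via `...` override values from the file (so callers play the role of
#' command-line flags).
#'
#' @param path config file, or `NULL` for pure-default/override use.
#' @param ... overrides passed straight to [pipeline_config()].
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path = NULL, ...) {
  opts <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*", "", lines)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      opts[[key]] <- if (!is.na(num)) num else val
    }
  }
  overrides <- list(...)
  opts[names(overrides)] <- overrides
  do.call(pipeline_config, opts)
}

#' Run the full denoising and chimera-removal pipeline
#'
#' Filter -> flowgram EM denoising -> sequence EM denoising -> chimera
#' classification, with every raw read traceable to its final fate. The run
#' is deterministic given the inputs and configuration.
#'
#' @param flowgrams list of [flowgram] objects, or a path readable by
#'   [read_flowgrams()].
#' @param config a [pipeline_config()].
#' @return an object of class `"amplicon_pipeline"` with elements `filter`
#'   (kept count and rejection log), `pyronoise`, `seqnoise`, `perseus` (the
#'   stage fits), `sequences` (data frame of final non-chimeric sequences
#'   with frequencies), and `provenance` (per raw read: fate and the
#'   component it reached at each stage).
#' @export
run_pipeline <- function(flowgrams, config = pipeline_config()) {
  if (is.character(flowgrams)) flowgrams <- read_flowgrams(flowgrams)
  stopifnot(inherits(config, "pipeline_config"), length(flowgrams) > 0)
  policy <- filter_policy(config$platform, primer = config$primer,
                          tag = config$tag,
                          end_truncation_flow = config$truncate_flows)
  filt <- filter_flowgrams(flowgrams, policy)
  if (length(filt$kept) == 0) {
    stop("pipeline stage 'filter': no reads passed filtering")
  }
  model <- if (is.null(config$intensity_model)) default_intensity_model()
           else config$intensity_model
  tm <- transition_model(config$transition_probs, config$gap, config$hgap)

  pn <- pyronoise(filt$kept, model, sigma_p = config$sigma_p,
                  cut_p = config$cut_p, max_iter = config$max_iter,
                  tol = config$tol)
  sn <- seqnoise(denoised_sequences(pn), tm, sigma_s = config$sigma_s,
                 cut_s = config$cut_s, truncate_len = config$truncate_bases,
                 max_iter = config$max_iter, tol = config$tol)
  ps <- perseus(denoised_sequences(sn), tm,
                logistic_model(config$alpha, config$beta),
                config$dist_threshold)

  chimeric_ids <- ps$id[ps$chimeric]
  comp <- sn$components
  final <- comp[!comp$id %in% chimeric_ids,
                c("id", "sequence", "frequency"), drop = FALSE]

  prov <- data.frame(read_id = vapply(flowgrams, `[[`, character(1), "id"),
                     fate = NA_character_, stage1 = NA_character_,
                     stage2 = NA_character_, stringsAsFactors = FALSE)
  if (nrow(filt$rejections)) {
    i <- match(filt$rejections$read_id, prov$read_id)
    prov$fate[i] <- paste0("rejected: ", filt$rejections$reason)
  }
  i1 <- match(pn$mapping$read_id, prov$read_id)
  prov$stage1[i1] <- pn$mapping$component
  s2 <- sn$mapping$component[match(prov$stage1, sn$mapping$input_id)]
  prov$stage2 <- s2
  kept_mask <- !is.na(prov$stage2)
  prov$fate[kept_mask] <- ifelse(prov$stage2[kept_mask] %in% chimeric_ids,
                                 "removed as chimera",
                                 paste0("denoised to ", prov$stage2[kept_mask]))
  stopifnot(sum(is.na(prov$fate)) == 0)

  structure(
    list(filter = list(n_kept = length(filt$kept),
                       rejections = filt$rejections),
         pyronoise = pn, seqnoise = sn, perseus = ps,
         sequences = final, provenance = prov, config = config),
    class = "amplicon_pipeline"
  )
}

#' @export
print.amplicon_pipeline <- function(x, ...) {
  n <- nrow(x$provenance)
  cat("Amplicon denoising pipeline (", x$config$platform, ")\n", sep = "")
  cat("  input reads:       ", n, "\n")
  cat("  passed filtering:  ", x$filter$n_kept, "\n")
  cat("  stage-1 components:", nrow(x$pyronoise$components), "\n")
  cat("  stage-2 components:", nrow(x$seqnoise$components), "\n")
  cat("  flagged chimeric:  ", sum(x$perseus$chimeric), "\n")
  cat("  final sequences:   ", nrow(x$sequences), "\n")
  invisible(x)
}
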