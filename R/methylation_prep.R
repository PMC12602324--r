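#' Methylation probe filtering and winsorization
#'
#' Probe-level preparation of a beta-value matrix (subjects x CpGs):
#' variability scoring by median absolute deviation, removal of
#' cross-reactive probes, restriction to probes shared across array types,
#' and per-probe 3-IQR winsorization of beta values.
#'
#' @name methylation_prep
NULL

#' Median absolute deviation per probe
#'
#' MAD on the beta scale: the median of absolute deviations from the probe
#' median (no consistency constant, matching how array variability is
#' conventionally reported).
#'
#' @param betas Numeric matrix, subjects x probes.
#' @return Named numeric vector of per-probe MAD scores.
#' @export
mad_score <- function(betas) {
  betas <- as.matrix(betas)
  bad <- colSums(!is.na(betas)) == 0L
  if (any(bad)) {
    stop("mad_score: all-missing probe(s): ",
         paste(colnames(betas)[bad], collapse = ", "))
  }
  apply(betas, 2L, function(x) {
    x <- x[!is.na(x)]
    stats::median(abs(x - stats::median(x)))
  })
}

#' Probe filtering
#'
#' Sequentially drops (1) probes on the cross-reactive list, (2) probes
#' failing the variability rule, (3) probes absent from the shared-probe
#' (both-array) list, logging the count removed at each step. The
#' variability rule is either a MAD threshold (`mad_min`) or retention of the
#' top `top_k` probes by MAD; `NULL` disables a rule.
#'
#' @param betas Beta matrix, subjects x probes.
#' @param cross_reactive Character vector of probe ids to remove (optional).
#' @param mad_min Minimum MAD to retain (optional).
#' @param top_k Retain only the `top_k` most variable probes by MAD
#'   (optional; applied after `mad_min` if both are set).
#' @param shared_probes Character vector of probes present and passing QC on
#'   both array types (optional).
#' @return List with `keep` (retained probe ids, input order), `drops`
#'   (named integer vector: `cross_reactive`, `variability`, `not_shared`)
#'   and `n_input`.
#' @export
probe_filter <- function(betas, cross_reactive = NULL, mad_min = NULL,
                         top_k = NULL, shared_probes = NULL) {
  probes <- colnames(betas)
  alive <- rep(TRUE, length(probes))
  drops <- c(cross_reactive = 0L, variability = 0L, not_shared = 0L)

  if (!is.null(cross_reactive)) {
    bad <- alive & probes %in% cross_reactive
    drops["cross_reactive"] <- sum(bad)
    alive <- alive & !bad
  }
  if (!is.null(mad_min) || !is.null(top_k)) {
    mads <- mad_score(betas[, alive, drop = FALSE])
    pass <- rep(TRUE, length(mads))
    if (!is.null(mad_min)) pass <- pass & mads >= mad_min
    if (!is.null(top_k) && sum(pass) > top_k) {
      ord <- order(-mads, seq_along(mads))      # ties: earlier probe wins
      in_top <- ord[seq_len(top_k)]
      pass <- pass & seq_along(mads) %in% in_top
    }
    bad_ids <- names(mads)[!pass]
    bad <- alive & probes %in% bad_ids
    drops["variability"] <- sum(bad)
    alive <- alive & !bad
  }
  if (!is.null(shared_probes)) {
    bad <- alive & !(probes %in% shared_probes)
    drops["not_shared"] <- sum(bad)
    alive <- alive & !bad
  }
  list(keep = probes[alive], drops = drops, n_input = length(probes))
}

#' Winsorize beta values per probe
#'
#' Applies the 3-IQR winsorization rule (see [winsorize_iqr()]) independently
#' to every probe column.
#'
#' @param betas Beta matrix, subjects x probes, >= 4 subjects.
#' @param multiplier IQR multiplier (default 3).
#' @return Matrix of the same shape with per-probe outliers clipped.
#' @export
winsorize_betas <- function(betas, multiplier = 3) {
  betas <- as.matrix(betas)
  if (nrow(betas) < 4L) stop("winsorize_betas: need at least 4 subjects")
  apply(betas, 2L, winsorize_iqr, multiplier = multiplier)
}
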