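#' Specify a synthetic two-sample RPPA table
#'
#' Describes a panel of antibody endpoints with planted fold changes on a
#' subset of proteins, log-normal multiplicative measurement noise, and
#' optional multiple phosphosite endpoints per protein. Baseline (l-OS)
#' intensities are uniform on `baseline_range`, mirroring the scale of the
#' patient panel (roughly 1e3 to 7e4 arbitrary units); the s-OS intensity of
#' an endpoint on protein `p` is `l_OS * fold(p) * exp(N(0, noise_sigma))`,
#' with `fold(p) = 1` for unplanted proteins.
#'
#' @param n_endpoints total number of endpoints in the panel.
#' @param planted_up named numeric vector: protein name -> fold (> 1),
#'   proteins up-regulated in the short-survival sample.
#' @param planted_down named numeric vector: protein name -> fold (> 1),
#'   applied as `1/fold` (down in s-OS).
#' @param noise_sigma standard deviation of the log-normal noise, in log
#'   units (>= 0).
#' @param baseline_range length-2 interval for baseline intensities.
#' @param phosphosites named integer vector: proteins measured by more than
#'   one phosphosite antibody (each extra site is an extra endpoint drawn
#'   with the same fold and independent noise).
#' @return An object of class `synthetic_rppa_spec`.
#' @export
synthetic_rppa_spec <- function(n_endpoints,
                                planted_up = numeric(0),
                                planted_down = numeric(0),
                                noise_sigma = 0.2,
                                baseline_range = c(1e3, 7e4),
                                phosphosites = integer(0)) {
  if (!is.numeric(n_endpoints) || n_endpoints < 1) {
    stop("invalid spec: n_endpoints must be a positive count")
  }
  if (length(planted_up) > 0 &&
      (is.null(names(planted_up)) || any(planted_up <= 1))) {
    stop("invalid spec: planted_up must be a named vector of folds > 1")
  }
  if (length(planted_down) > 0 &&
      (is.null(names(planted_down)) || any(planted_down <= 1))) {
    stop("invalid spec: planted_down must be a named vector of folds > 1")
  }
  if (length(intersect(names(planted_up), names(planted_down))) > 0) {
    stop("invalid spec: planted_up and planted_down must be disjoint")
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("invalid spec: noise_sigma must be >= 0")
  }
  if (length(baseline_range) != 2 || baseline_range[1] <= 0 ||
      baseline_range[2] <= baseline_range[1]) {
    stop("invalid spec: baseline_range must be a positive increasing interval")
  }
  structure(
    list(n_endpoints = n_endpoints, planted_up = planted_up,
         planted_down = planted_down, noise_sigma = noise_sigma,
         baseline_range = baseline_range,
         phosphosites = phosphosites),
    class = "synthetic_rppa_spec"
  )
}

#' Generate a synthetic two-sample RPPA table
#'
#' Draws a reproducible `rppa_table` from a [synthetic_rppa_spec()]. Every
#' protein contributes one endpoint per phosphosite (default one); the total
#' endpoint count equals `n_endpoints`, with unplanted single-site proteins
#' filling the remainder.
#'
#' @param spec a `synthetic_rppa_spec`.
#' @param seed integer RNG seed; the same seed yields an identical table.
#' @return A list-based `rppa_table` (as from [load_rppa_table()]) with an
#'   extra `truth` data.frame (`protein`, `planted`, `fold`) and a `mapping`
#'   data.frame usable with [aggregate_phosphosites()].
#' @export
generate_rppa_table <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_rppa_spec"))
  planted <- c(spec$planted_up, 1 / spec$planted_down)
  n_sites <- function(p) {
    if (p %in% names(spec$phosphosites)) {
      max(1L, as.integer(spec$phosphosites[[p]]))
    } else 1L
  }
  planted_sites <- sum(vapply(names(planted), n_sites, integer(1)))
  if (length(planted) > 0 && planted_sites > spec$n_endpoints) {
    stop("invalid spec: planted endpoints exceed n_endpoints")
  }
  extra_sites <- sum(vapply(names(spec$phosphosites), function(p) {
    if (p %in% names(planted)) 0L
    else max(0L, as.integer(spec$phosphosites[[p]]) - 1L)
  }, integer(1)))
  n_null <- spec$n_endpoints - planted_sites - extra_sites
  if (n_null < 0) stop("invalid spec: phosphosite endpoints exceed n_endpoints")

  null_names <- setdiff(
    sprintf("prot%04d", seq_len(length(planted) + n_null + 10)),
    names(planted)
  )
  multi_null <- setdiff(names(spec$phosphosites), names(planted))
  n_single_null <- n_null - length(multi_null)
  if (n_single_null < 0) stop("invalid spec: phosphosite endpoints exceed n_endpoints")
  proteins <- c(names(planted), multi_null,
                null_names[seq_len(n_single_null)])
  fold <- c(planted, stats::setNames(rep(1, length(multi_null) + n_single_null),
                                     c(multi_null, null_names[seq_len(n_single_null)])))

  rows <- do.call(rbind, lapply(proteins, function(p) {
    data.frame(protein = p, site = seq_len(n_sites(p)),
               stringsAsFactors = FALSE)
  }))
  stopifnot(nrow(rows) == spec$n_endpoints)

  set.seed(as.integer(seed))
  l_os <- stats::runif(nrow(rows), spec$baseline_range[1], spec$baseline_range[2])
  eps <- stats::rnorm(nrow(rows), 0, spec$noise_sigma)
  s_os <- l_os * fold[rows$protein] * exp(eps)

  antibody <- sprintf("%s (S%d)", rows$protein, rows$site)
  rc <- compute_ratio(l_os, s_os)
  endpoints <- data.frame(
    catalog_id = sprintf("SYN%04d", seq_len(nrow(rows))),
    antibody = antibody,
    value_lOS = l_os,
    value_sOS = s_os,
    ratio = ifelse(rc$flag == "zero", 0, rc$ratio),
    flag = rc$flag,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    protein = proteins,
    planted = proteins %in% names(planted),
    fold = as.numeric(fold[proteins]),
    stringsAsFactors = FALSE
  )
  mapping <- data.frame(antibody = antibody, node = rows$protein,
                        excluded = FALSE, stringsAsFactors = FALSE)
  structure(
    list(endpoints = endpoints, sample_labels = c("l-OS", "s-OS"),
         truth = truth, mapping = mapping, spec = spec, seed = seed),
    class = c("synthetic_rppa_table", "rppa_table")
  )
}
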