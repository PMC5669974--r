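#' Compute s-OS / l-OS intensity ratios
#'
#' The divergence statistic of the two-sample RPPA comparison: the short-
#' survival intensity divided by the long-survival intensity. Degenerate
#' intensities are flagged rather than silently propagated: a positive
#' numerator over a zero denominator is `"undefined-high"` (divergent upward
#' but with no finite ratio), a zero over a positive denominator is a genuine
#' ratio of `0` (flag `"zero"`), and `0/0` is `"uninformative"`.
#'
#' @param value_lOS,value_sOS non-negative intensity vectors (arbitrary units)
#'   for the long- and short-survival sample.
#' @return A data.frame with columns `ratio` (numeric, `NA` where no finite
#'   ratio exists) and `flag` (`"ok"`, `"zero"`, `"undefined-high"` or
#'   `"uninformative"`).
#' @examples
#' compute_ratio(c(25336.48, 36680.49, 2), c(6075.38, 0, 2))
#' @export
compute_ratio <- function(value_lOS, value_sOS) {
  if (length(value_lOS) != length(value_sOS)) {
    stop("value_lOS and value_sOS must have the same length")
  }
  if (any(!is.finite(value_lOS)) || any(!is.finite(value_sOS))) {
    stop("intensities must be finite")
  }
  if (any(value_lOS < 0) || any(value_sOS < 0)) {
    stop("intensities must be non-negative")
  }
  ratio <- ifelse(value_lOS > 0, value_sOS / value_lOS, NA_real_)
  flag <- rep("ok", length(ratio))
  flag[value_lOS > 0 & value_sOS == 0] <- "zero"
  flag[value_lOS == 0 & value_sOS > 0] <- "undefined-high"
  flag[value_lOS == 0 & value_sOS == 0] <- "uninformative"
  data.frame(ratio = ratio, flag = flag, stringsAsFactors = FALSE)
}

#' Load a two-sample RPPA endpoint table
#'
#' Reads a CSV/TSV table with one antibody endpoint per row and the paired
#' long-survival (`l_OS`) and short-survival (`s_OS`) intensities, recomputes
#' the s-OS/l-OS ratio from the raw values, and (when a `printed_ratio`
#' column is present) cross-checks the recomputed ratios against the printed
#' ones to 2 decimals, warning about any mismatch.
#'
#' The fixture shipped with the package
#' (`system.file("extdata", "rppa_table1.csv", package = "pathwayCRA")`)
#' holds the 51-endpoint panel of the two lung adenocarcinoma patients.
#'
#' @param path path to the table.
#' @param sep field delimiter; by default inferred from the file extension
#'   (`.tsv`/`.txt` gives tab, anything else comma).
#' @return An object of class `rppa_table`: a list with `endpoints` (a
#'   data.frame with `catalog_id`, `antibody`, `value_lOS`, `value_sOS`,
#'   `ratio`, `flag`) and `sample_labels`.
#' @export
load_rppa_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("RPPA table not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("catalog_id", "antibody", "l_OS", "s_OS")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("RPPA table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) stop("RPPA table format error: no endpoint rows")
  if (anyDuplicated(raw$antibody)) {
    stop("RPPA table validation error: duplicated antibody name(s): ",
         paste(unique(raw$antibody[duplicated(raw$antibody)]), collapse = ", "))
  }
  lv <- as.numeric(raw$l_OS)
  sv <- as.numeric(raw$s_OS)
  if (any(is.na(lv)) || any(is.na(sv))) {
    stop("RPPA table validation error: non-numeric intensity")
  }
  if (any(lv < 0) || any(sv < 0)) {
    stop("RPPA table validation error: negative intensity")
  }
  rc <- compute_ratio(lv, sv)
  ratio_for_check <- ifelse(rc$flag == "zero", 0, rc$ratio)
  if ("printed_ratio" %in% names(raw)) {
    printed <- as.numeric(raw$printed_ratio)
    checkable <- lv > 0 & !is.na(printed)
    off <- checkable &
      abs(round(ratio_for_check, 2) - round(printed, 2)) > 0.005
    if (any(off)) {
      warning("printed ratio differs from recomputed ratio for: ",
              paste(raw$antibody[off], collapse = ", "))
    }
  }
  endpoints <- data.frame(
    catalog_id = as.character(raw$catalog_id),
    antibody = raw$antibody,
    value_lOS = lv,
    value_sOS = sv,
    ratio = ifelse(rc$flag == "zero", 0, rc$ratio),
    flag = rc$flag,
    stringsAsFactors = FALSE
  )
  structure(
    list(endpoints = endpoints, sample_labels = c("l-OS", "s-OS")),
    class = "rppa_table"
  )
}

#' @export
print.rppa_table <- function(x, ...) {
  cat("RPPA two-sample table:", nrow(x$endpoints), "endpoints (",
      paste(x$sample_labels, collapse = " vs "), ")\n")
  invisible(x)
}

#' Select divergent endpoints by a fold-change rule
#'
#' Flags endpoints whose s-OS/l-OS ratio is at least `fold` (up in the
#' short-survival sample) or at most `1/fold` (down). An `"undefined-high"`
#' ratio (zero l-OS, positive s-OS) counts as up; a true zero ratio counts as
#' down; `"uninformative"` endpoints (0/0) are never selected. The default
#' 2-fold rule reproduces the 20 divergent endpoints (4 up, 16 down) of the
#' shipped patient panel.
#'
#' @param table an `rppa_table`.
#' @param fold fold-change threshold, strictly greater than 1 (default 2).
#' @return An object of class `divergence_selection` with data.frames
#'   `up_in_sOS` and `down_in_sOS` and the counts.
#' @export
select_divergent <- function(table, fold = 2) {
  stopifnot(inherits(table, "rppa_table"))
  if (!is.numeric(fold) || length(fold) != 1 || fold <= 1) {
    stop("fold must be a single number > 1")
  }
  ep <- table$endpoints
  up <- (ep$flag == "undefined-high") | (!is.na(ep$ratio) & ep$ratio >= fold)
  down <- !is.na(ep$ratio) & ep$ratio <= 1 / fold & ep$flag != "uninformative"
  structure(
    list(
      up_in_sOS = ep[up, , drop = FALSE],
      down_in_sOS = ep[down, , drop = FALSE],
      n_divergent = sum(up) + sum(down),
      n_up = sum(up),
      n_down = sum(down),
      fold = fold
    ),
    class = "divergence_selection"
  )
}

#' @export
print.divergence_selection <- function(x, ...) {
  cat("Divergent endpoints at ", x$fold, "-fold: ", x$n_divergent,
      " (", x$n_up, " up, ", x$n_down, " down in s-OS)\n", sep = "")
  if (!is.null(x$calibration_proteins)) {
    cp <- x$calibration_proteins
    cat("Calibration proteins:",
        paste0(cp$node, " (", cp$direction, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load an antibody-to-model-node mapping
#'
#' @param path CSV with columns `antibody`, `node`, `excluded` (logical);
#'   defaults to the mapping shipped for the 51-endpoint patient panel.
#' @return data.frame with those columns.
#' @export
load_antibody_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "antibody_node_map.csv",
                        package = "pathwayCRA")
  }
  if (!file.exists(path)) stop("antibody map not found: ", path)
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("antibody", "node", "excluded")
  missing <- setdiff(required, names(map))
  if (length(missing) > 0) {
    stop("antibody map format error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  map$excluded <- as.logical(map$excluded)
  map
}

# Join endpoints to their model nodes, dropping excluded antibodies.
# Errors if any endpoint is absent from the mapping.
map_endpoints <- function(table, mapping) {
  ep <- table$endpoints
  unmapped <- setdiff(ep$antibody, mapping$antibody)
  if (length(unmapped) > 0) {
    stop("antibody mapping error: unmapped antibodies: ",
         paste(unmapped, collapse = ", "))
  }
  idx <- match(ep$antibody, mapping$antibody)
  ep$node <- mapping$node[idx]
  ep$excluded <- mapping$excluded[idx]
  ep[!ep$excluded & !is.na(ep$node) & ep$node != "", , drop = FALSE]
}

#' Aggregate phosphosite endpoints to per-node activation ratios
#'
#' Multiple phosphosite antibodies that map to the same model node are
#' combined by the geometric mean of their finite ratios (an average on the
#' log scale, where fold changes are symmetric). Endpoints flagged excluded
#' in the mapping (total-protein antibodies, off-model proteins) are dropped;
#' endpoints without a finite positive ratio do not enter the mean, and a
#' node whose endpoints are all non-finite is returned with `NA` and flagged.
#'
#' @param table an `rppa_table`.
#' @param mapping antibody-to-node map as from [load_antibody_map()].
#' @return data.frame with one row per node: `node`, `ratio` (geometric
#'   mean), `n_endpoints`, `n_finite`, `flag` (`"ok"` or `"no-finite-ratio"`).
#' @export
aggregate_phosphosites <- function(table, mapping) {
  stopifnot(inherits(table, "rppa_table"))
  mapped <- map_endpoints(table, mapping)
  nodes <- unique(mapped$node)
  res <- lapply(nodes, function(nd) {
    sub <- mapped[mapped$node == nd, , drop = FALSE]
    finite <- sub$flag == "ok" & !is.na(sub$ratio) & sub$ratio > 0
    gm <- if (any(finite)) exp(mean(log(sub$ratio[finite]))) else NA_real_
    data.frame(node = nd, ratio = gm, n_endpoints = nrow(sub),
               n_finite = sum(finite),
               flag = if (any(finite)) "ok" else "no-finite-ratio",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$node), , drop = FALSE]
}

#' Select the calibration proteins
#'
#' Ranks model-mapped proteins by their most divergent endpoint and picks the
#' `k_per_side` most up-regulated and most down-regulated nodes in the
#' short-survival sample. Divergence is `|log2(ratio)|`; an endpoint with an
#' `"undefined-high"` ratio ranks most extreme on the up side and a zero
#' ratio most extreme on the down side. Each node is assigned to the side of
#' its most divergent endpoint, so a node can only be selected on one side.
#' On the shipped patient panel with the default 21-node model this yields
#' BAD and cKIT ("+", higher in s-OS) and RAF and p70S6K ("-", lower).
#'
#' @param table an `rppa_table`.
#' @param mapping antibody-to-node map; see [load_antibody_map()].
#' @param model_nodes character vector of model node names; endpoints mapping
#'   elsewhere are ignored.
#' @param k_per_side number of proteins per direction (default 2).
#' @param fold divergence threshold forwarded to [select_divergent()].
#' @return A `divergence_selection` whose `calibration_proteins` data.frame
#'   has columns `node`, `direction` (`"+"`/`"-"`) and `score` (the node's
#'   most divergent endpoint ratio, `Inf`/`0` for flagged extremes).
#' @export
select_calibration_proteins <- function(table, mapping, model_nodes,
                                        k_per_side = 2, fold = 2) {
  stopifnot(inherits(table, "rppa_table"))
  if (!is.numeric(k_per_side) || k_per_side < 1) {
    stop("k_per_side must be at least 1")
  }
  mapped <- map_endpoints(table, mapping)
  mapped <- mapped[mapped$node %in% model_nodes, , drop = FALSE]
  if (nrow(mapped) == 0) stop("selection error: no model-mapped endpoints")

  # per-endpoint signed divergence on the log2 scale
  lr <- ifelse(mapped$flag == "undefined-high", Inf,
        ifelse(mapped$ratio == 0, -Inf, log2(mapped$ratio)))
  nodes <- unique(mapped$node)
  score <- vapply(nodes, function(nd) {
    v <- lr[mapped$node == nd]
    v[which.max(abs(v))]
  }, numeric(1))
  score <- score[abs(score) > 0]            # ratio exactly 1 is not divergent
  up <- sort(score[score > 0], decreasing = TRUE)
  down <- sort(score[score < 0])
  if (length(up) < k_per_side || length(down) < k_per_side) {
    stop("selection error: fewer than ", k_per_side,
         " divergent model-mapped proteins on one side")
  }
  up <- up[seq_len(k_per_side)]
  down <- down[seq_len(k_per_side)]
  cp <- data.frame(
    node = c(names(up), names(down)),
    direction = c(rep("+", k_per_side), rep("-", k_per_side)),
    score = 2^c(up, down),
    stringsAsFactors = FALSE
  )
  sel <- select_divergent(table, fold = fold)
  sel$calibration_proteins <- cp
  sel
}
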