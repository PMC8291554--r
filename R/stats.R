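#' The 14 subcortical regions of the activation analysis
#' @export
visor_regions <- c("BMA", "MEA", "VMH", "DMH", "CEA", "BLA", "PMv",
                   "AHN", "ZI", "PVH", "TU", "SUM", "PH", "LHA")

check_table <- function(table) {
  req <- c("animal_id", "group", "region", "count")
  if (!all(req %in% names(table)))
    stop("activation table needs columns ", paste(req, collapse = ", "))
  if (any(table$count < 0)) stop("counts must be nonnegative")
  table$group <- as.character(table$group)
  table
}

#' Relative z-scores of activated-cell counts
#'
#' For every animal and region, z = (x - mean_ctrl) / SD_ctrl, where the
#' mean and (sample, n-1 denominator) standard deviation are taken over
#' the control animals of that region. Control columns therefore have
#' sample mean 0 and sample SD 1 exactly. Regions whose control SD is
#' zero are flagged undefined (NA).
#'
#' @param table long activation table: columns \code{animal_id},
#'   \code{group} ("FST" or "control"), \code{region}, \code{count}.
#' @param control name of the control group.
#' @return the table with a \code{z} column added.
#' @export
relative_zscore <- function(table, control = "control") {
  table <- check_table(table)
  out <- table
  out$z <- NA_real_
  for (r in unique(table$region)) {
    sel <- table$region == r
    ctrl <- table$count[sel & table$group == control]
    if (length(ctrl) < 2) stop("need >= 2 control animals in region ", r)
    s <- stats::sd(ctrl)
    if (s > 0) out$z[sel] <- (table$count[sel] - mean(ctrl)) / s
  }
  out
}

#' Coefficient of variation per region within one group
#'
#' CV = SD / mean (sample SD). Regions with zero mean are flagged NA.
#'
#' @param table long activation table.
#' @param group group to summarize.
#' @return data.frame (region, cv).
#' @export
coefficient_of_variation <- function(table, group) {
  table <- check_table(table)
  tab <- table[table$group == group, , drop = FALSE]
  regs <- unique(table$region)
  cv <- vapply(regs, function(r) {
    x <- tab$count[tab$region == r]
    m <- mean(x)
    if (!length(x) || m <= 0) NA_real_ else stats::sd(x) / m
  }, 1)
  data.frame(region = regs, cv = unname(cv))
}

# exact permutation p-value for a mean difference (used when both groups
# are degenerate-variance so the t statistic is undefined)
perm_p <- function(x, y, n_max = 20000L) {
  obs <- abs(mean(x) - mean(y))
  all_ <- c(x, y); nx <- length(x)
  idx <- utils::combn(length(all_), nx)
  if (ncol(idx) > n_max) idx <- idx[, sample.int(ncol(idx), n_max)]
  stat <- apply(idx, 2, function(s) abs(mean(all_[s]) - mean(all_[-s])))
  mean(stat >= obs - 1e-12)
}

#' Storey-style q-values
#'
#' BH-type q-values rescaled by the estimated null fraction pi0 =
#' #\{p > lambda\} / (m (1 - lambda)), capped at 1.
#'
#' @param p p-values.
#' @param lambda tuning parameter in (0, 1).
#' @return q-values.
#' @export
qvalue_storey <- function(p, lambda = 0.5) {
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pmin(1, pi0 * stats::p.adjust(p, "BH"))
}

#' Per-region two-group tests with FDR q-values
#'
#' Welch two-sample t-tests comparing the two groups region by region,
#' fold changes (mean ratio), per-group CVs, and multiple-testing
#' q-values across the regions (Benjamini-Hochberg by default, Storey
#' option). Regions where both groups have zero variance fall back to an
#' exact permutation p-value.
#'
#' @param table long activation table.
#' @param group1,group2 names of the test and reference groups.
#' @param fdr "bh" or "storey".
#' @return data.frame of class \code{visor_stats}: region, n per group,
#'   means, fold_change, cv per group, t, p, q.
#' @export
group_test <- function(table, group1 = "FST", group2 = "control",
                       fdr = c("bh", "storey")) {
  table <- check_table(table)
  fdr <- match.arg(fdr)
  regs <- unique(table$region)
  rows <- lapply(regs, function(r) {
    x <- table$count[table$region == r & table$group == group1]
    y <- table$count[table$region == r & table$group == group2]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 animals per group in region ", r)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      tv <- NA_real_
      pv <- if (mean(x) == mean(y)) 1 else perm_p(x, y)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      tv <- unname(tt$statistic); pv <- tt$p.value
    }
    data.frame(region = r, n1 = length(x), n2 = length(y),
               mean1 = mean(x), mean2 = mean(y),
               fold_change = if (mean(y) > 0) mean(x) / mean(y) else NA_real_,
               cv1 = if (mean(x) > 0) stats::sd(x) / mean(x) else NA_real_,
               cv2 = if (mean(y) > 0) stats::sd(y) / mean(y) else NA_real_,
               t = tv, p = pv)
  })
  out <- do.call(rbind, rows)
  out$q <- switch(fdr, bh = stats::p.adjust(out$p, "BH"),
                  storey = qvalue_storey(out$p))
  class(out) <- c("visor_stats", class(out))
  attr(out, "groups") <- c(group1, group2)
  out
}

#' @export
print.visor_stats <- function(x, ...) {
  gr <- attr(x, "groups")
  cat(sprintf("Two-group activation statistics (%s vs %s), %d regions\n",
              gr[1], gr[2], nrow(x)))
  df <- as.data.frame(x)
  df$fold_change <- round(df$fold_change, 2)
  df$t <- round(df$t, 2); df$p <- signif(df$p, 3); df$q <- signif(df$q, 3)
  print(df[, c("region", "fold_change", "cv1", "cv2", "t", "p", "q")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Full cohort report: statistics, z-score matrix, CV comparison
#'
#' @param table long activation table.
#' @param group1,group2 test and reference group names.
#' @param fdr FDR method, see \code{\link{group_test}}.
#' @param csv_prefix when non-NULL, statistics and z-matrix are written
#'   to \code{<prefix>_stats.csv} and \code{<prefix>_zmatrix.csv}.
#' @param plot draw a z-matrix image and CV scatter (base graphics).
#' @return list of class \code{visor_report}: \code{stats},
#'   \code{z_matrix} (animals x regions), \code{cv} (region, cv1, cv2),
#'   \code{table} (with z).
#' @export
cohort_report <- function(table, group1 = "FST", group2 = "control",
                          fdr = "bh", csv_prefix = NULL, plot = FALSE) {
  table <- check_table(table)
  one_group <- length(unique(table$group)) < 2
  tz <- relative_zscore(table, control = group2)
  regs <- unique(table$region); ani <- unique(table$animal_id)
  zm <- matrix(NA_real_, length(ani), length(regs),
               dimnames = list(ani, regs))
  for (k in seq_len(nrow(tz)))
    zm[as.character(tz$animal_id[k]), as.character(tz$region[k])] <- tz$z[k]
  st <- if (one_group) NULL else group_test(table, group1, group2, fdr = fdr)
  cv <- data.frame(region = regs,
                   cv1 = coefficient_of_variation(table, group1)$cv,
                   cv2 = coefficient_of_variation(table, group2)$cv)
  if (!is.null(csv_prefix)) {
    if (!is.null(st))
      utils::write.csv(as.data.frame(st), paste0(csv_prefix, "_stats.csv"),
                       row.names = FALSE)
    utils::write.csv(as.data.frame(zm), paste0(csv_prefix, "_zmatrix.csv"))
  }
  out <- structure(list(stats = st, z_matrix = zm, cv = cv, table = tz),
                   class = "visor_report")
  if (plot) plot(out)
  out
}

#' @export
plot.visor_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  zm <- x$z_matrix
  graphics::image(seq_len(ncol(zm)), seq_len(nrow(zm)), t(zm),
                  xlab = "region", ylab = "animal", main = "relative z-score",
                  col = grDevices::hcl.colors(64, "Blue-Red"), axes = FALSE)
  graphics::axis(1, seq_len(ncol(zm)), colnames(zm), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(zm)), rownames(zm), las = 2, cex.axis = 0.6)
  ok <- stats::complete.cases(x$cv[, c("cv1", "cv2")])
  lim <- range(c(x$cv$cv1[ok], x$cv$cv2[ok]), 0)
  graphics::plot(x$cv$cv2[ok], x$cv$cv1[ok], xlim = lim, ylim = lim,
                 xlab = "CV control", ylab = "CV test", main = "CV")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate an activation cohort
#'
#' Generates per-animal, per-region activated-cell counts for a
#' two-group cohort (default 8 test + 8 control animals over the 14
#' regions). Counts are truncated-normal draws. The default effect
#' structure mirrors an acute-stress experiment: a few regions get a
#' mean shift of \code{effect_sd} control SDs in the test group, and
#' most of the remaining regions get inflated test-group variability
#' (higher CV), with one shifted region given reduced variability (a
#' ceiling-like effect).
#'
#' @param n_per_group animals per group.
#' @param regions region names.
#' @param base_mean named (or unnamed, recycled) control means.
#' @param base_cv control coefficient of variation.
#' @param shifted_regions regions with a true mean shift.
#' @param effect_sd shift size in control SDs.
#' @param var_regions regions with inflated test-group SD; defaults to
#'   all non-shifted regions except the last.
#' @param var_factor SD inflation factor for \code{var_regions}.
#' @param ceiling_region region given reduced test variability.
#' @param null when TRUE, both groups are drawn from the identical
#'   control distribution (global null).
#' @param seed RNG seed.
#' @return long activation table (animal_id, group, region, count).
#' @export
simulate_cohort <- function(n_per_group = 8L, regions = visor_regions,
                            base_mean = 800, base_cv = 0.25,
                            shifted_regions = c("BMA", "MEA", "VMH"),
                            effect_sd = 3, var_regions = NULL,
                            var_factor = 2, ceiling_region = "VMH",
                            null = FALSE, seed = 1L) {
  set.seed(seed)
  m <- length(regions)
  mu <- rep_len(base_mean, m); names(mu) <- regions
  sd0 <- base_cv * mu
  if (is.null(var_regions))
    var_regions <- setdiff(regions, c(shifted_regions, regions[m]))
  rows <- list()
  for (g in c("FST", "control")) for (a in seq_len(n_per_group)) {
    id <- paste0(substr(g, 1, 1), a)
    for (r in regions) {
      mean_r <- mu[r]; sd_r <- sd0[r]
      if (g == "FST" && !null) {
        if (r %in% shifted_regions) mean_r <- mean_r + effect_sd * sd0[r]
        if (r %in% var_regions) sd_r <- sd_r * var_factor
        if (identical(r, ceiling_region)) sd_r <- sd0[r] * 0.5
      }
      rows[[length(rows) + 1L]] <-
        data.frame(animal_id = id, group = g, region = r,
                   count = max(0, round(stats::rnorm(1, mean_r, sd_r))))
    }
  }
  do.call(rbind, rows)
}
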