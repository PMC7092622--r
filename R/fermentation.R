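#' Growth parameters for the synthetic bioreactor generator
#'
#' Defaults reproduce the two published fed-batch conditions at pH 6 and
#' 0.1 MPa: on CO the culture reaches OD600 8.4 +/- 0.4 by 120 h and
#' accumulates 713 +/- 21 mM ethanol, 188 +/- 4 mM 2,3-butanediol and
#' 185 +/- 7 mM acetate; on H2/CO2 it peaks at OD 1.6 +/- 0.3 by 168 h
#' with 512 +/- 6 mM acetate and only 42 +/- 1 mM ethanol.  The logistic
#' rate and midpoint are not reported and are fixed here so the curves
#' saturate by the stated peak times.
#'
#' @param condition `"CO"` or `"H2_CO2"`.
#' @param od_max saturating OD600.
#' @param growth_rate logistic rate (1/h).
#' @param lag_midpoint logistic midpoint (h).
#' @param product_caps named numeric, end titers in mM.
#' @param noise_sd named numeric, additive replicate noise per product (mM).
#' @param od_noise_sd replicate noise on OD600.
#' @param seed integer RNG seed.
#' @return an object of class `"gf_growth_params"`.
#' @export
growth_params <- function(condition = c("CO", "H2_CO2"),
                          od_max = NULL, growth_rate = NULL,
                          lag_midpoint = NULL, product_caps = NULL,
                          noise_sd = NULL, od_noise_sd = NULL, seed = 1L) {
  condition <- match.arg(condition)
  def <- if (condition == "CO") {
    list(od_max = 8.4, growth_rate = 0.1, lag_midpoint = 48,
         product_caps = c(ethanol = 713, butanediol = 188, acetate = 185),
         noise_sd = c(ethanol = 21, butanediol = 4, acetate = 7),
         od_noise_sd = 0.4)
  } else {
    list(od_max = 1.6, growth_rate = 0.07, lag_midpoint = 60,
         product_caps = c(acetate = 512, ethanol = 42),
         noise_sd = c(acetate = 6, ethanol = 1),
         od_noise_sd = 0.3)
  }
  p <- list(condition = condition,
            od_max = if (is.null(od_max)) def$od_max else od_max,
            growth_rate = if (is.null(growth_rate)) def$growth_rate else growth_rate,
            lag_midpoint = if (is.null(lag_midpoint)) def$lag_midpoint else lag_midpoint,
            product_caps = if (is.null(product_caps)) def$product_caps else product_caps,
            noise_sd = if (is.null(noise_sd)) def$noise_sd else noise_sd,
            od_noise_sd = if (is.null(od_noise_sd)) def$od_noise_sd else od_noise_sd,
            seed = as.integer(seed))
  if (p$od_max <= 0) stop("od_max must be positive")
  if (p$growth_rate <= 0) stop("growth_rate must be positive")
  if (any(p$product_caps < 0)) stop("product caps must be non-negative")
  if (any(p$noise_sd < 0) || p$od_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (is.null(names(p$product_caps)))
    stop("product_caps must be named by product")
  structure(p, class = "gf_growth_params")
}

#' A fermentation time course
#'
#' @param condition feed condition label.
#' @param times sampling times in hours, strictly increasing.
#' @param od600 OD600 per time, non-negative.
#' @param products named list of concentration vectors (mM), non-negative.
#' @param replicate_sd named numeric of replicate spreads (mM), optional.
#' @return an object of class `"gf_timecourse"`.
#' @export
timecourse <- function(condition, times, od600, products,
                       replicate_sd = NULL) {
  if (length(times) == 0) stop("empty time series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(od600) != length(times)) stop("od600 length mismatch")
  if (any(od600 < 0)) stop("OD must be non-negative")
  for (p in names(products)) {
    if (length(products[[p]]) != length(times))
      stop("product '", p, "' length mismatch")
    if (any(products[[p]] < 0))
      stop("product '", p, "' has negative concentrations")
  }
  structure(list(condition = condition, times = times, od600 = od600,
                 products = products, replicate_sd = replicate_sd),
            class = "gf_timecourse")
}

#' Simulate a bioreactor time course
#'
#' OD and each product follow logistic curves sharing the growth midpoint
#' and rate (products are slaved to growth), saturating at `od_max` and the
#' product caps respectively; additive Gaussian replicate noise is applied
#' per sample and truncated at zero.  Identical seed gives identical
#' output.
#'
#' @param params a [growth_params()].
#' @param horizon_h total fermentation time (h); default 120 for CO,
#'   168 for H2/CO2.
#' @param step_h sampling interval (h); 12 h as in fed-batch practice.
#' @return a [timecourse()].
#' @export
simulate_fermentation <- function(params, horizon_h = NULL, step_h = 12) {
  if (!inherits(params, "gf_growth_params")) stop("params must be growth_params()")
  if (is.null(horizon_h))
    horizon_h <- if (params$condition == "CO") 120 else 168
  if (horizon_h <= 0 || step_h <= 0) stop("horizon and step must be positive")
  times <- seq(0, horizon_h, by = step_h)
  set.seed(params$seed)
  logi <- function(t) stats::plogis(params$growth_rate * (t - params$lag_midpoint))
  od <- pmax(0, params$od_max * logi(times) +
               stats::rnorm(length(times), 0, params$od_noise_sd))
  prods <- list()
  for (p in names(params$product_caps)) {
    sd_p <- if (p %in% names(params$noise_sd)) params$noise_sd[[p]] else 0
    prods[[p]] <- pmax(0, params$product_caps[[p]] * logi(times) +
                         stats::rnorm(length(times), 0, sd_p))
  }
  timecourse(params$condition, times, od, prods,
             replicate_sd = params$noise_sd)
}

#' End-product molar ratios
#'
#' Ratios of final concentrations relative to a reference product
#' (concentrations in mM are molar-proportional, so no conversion is
#' needed), with the nearest-integer rounding reported alongside.
#'
#' @param tc a [timecourse()].
#' @param reference_product product id with non-zero final concentration.
#' @param at `"end"` uses the final sample (default); `"peak"` uses each
#'   product's maximum, for non-monotone inputs.
#' @return a list with `ratios` (named numeric, reference = 1),
#'   `rounded` (nearest integers) and `reference`.
#' @export
end_product_ratios <- function(tc, reference_product = "acetate",
                               at = c("end", "peak")) {
  at <- match.arg(at)
  if (!reference_product %in% names(tc$products))
    stop("reference product '", reference_product, "' not in time course")
  final <- vapply(tc$products, function(x)
    if (at == "end") x[length(x)] else max(x), 0)
  ref <- final[[reference_product]]
  if (ref == 0)
    stop("reference product '", reference_product,
         "' has zero final concentration; cannot form ratios")
  ratios <- final / ref
  list(ratios = ratios, rounded = round(ratios),
       reference = reference_product)
}

#' Peak OD and its first attainment time
#' @param tc a [timecourse()].
#' @return list with `peak_od` and `time_of_peak` (first attainment).
#' @export
growth_summary <- function(tc) {
  if (length(tc$times) == 0) stop("empty time course")
  i <- which.max(tc$od600)
  list(peak_od = tc$od600[i], time_of_peak = tc$times[i])
}

.tc_columns <- function(products) {
  c("time_h", "od600", paste0(products, "_mM"))
}

#' Write a time course to CSV
#'
#' Header `time_h,od600,<product>_mM,...`, preceded by a `# condition=`
#' comment line.
#'
#' @param tc a [timecourse()].
#' @param path output file.
#' @export
write_timecourse <- function(tc, path) {
  df <- data.frame(time_h = tc$times, od600 = tc$od600)
  for (p in names(tc$products)) df[[paste0(p, "_mM")]] <- tc$products[[p]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# condition=", tc$condition), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time course from CSV
#'
#' @param path CSV with header `time_h,od600,<product>_mM,...`; an optional
#'   leading `# condition=` comment is honoured.  Malformed rows, missing
#'   columns and non-increasing times raise errors naming the problem.
#' @return a [timecourse()].
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("time-course file not found: ", path)
  lines <- readLines(path)
  condition <- "unknown"
  if (length(lines) > 0 && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("condition=([^ ]+)", lines[1]))[[1]]
    if (length(m) == 2) condition <- m[2]
    lines <- lines[-1]
  }
  if (length(lines) < 1) stop("time-course file has no header")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  for (col in c("time_h", "od600"))
    if (!col %in% header) stop("missing column '", col, "'")
  body <- lines[-1]
  body <- body[nzchar(body)]
  vals <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop("malformed row at line ", i + 1 + (condition != "unknown"),
           ": expected ", length(header), " fields, got ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop("malformed row at line ", i + 1 + (condition != "unknown"),
           ": non-numeric value")
    v
  })
  mat <- do.call(rbind, vals)
  colnames(mat) <- header
  prod_cols <- grep("_mM$", header, value = TRUE)
  products <- lapply(prod_cols, function(cl) mat[, cl])
  names(products) <- sub("_mM$", "", prod_cols)
  timecourse(condition, mat[, "time_h"], mat[, "od600"], products)
}
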