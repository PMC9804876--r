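#' Weight configuration for consequence-based variant weighting
#'
#' A weight configuration maps VEP-style consequence terms to positive
#' functional weights (more severe predicted impact, higher weight) and to
#' broader variant categories used by the category-level tests. It also
#' carries the parameters of the minor-allele-frequency (MAF) weight: rare
#' variants at the MAF cap receive `maf_weight_min` and variants with MAF
#' close to zero receive `maf_weight_max`, interpolated linearly in between.
#'
#' The default configuration anchors stop-gained (and other loss-of-function
#' terms) at weight 100 and missense at weight 5, with a severity-ordered
#' table for the remaining terms; categories are `LOF`, `protein_altering`,
#' `splice_site`, `intronic` and `synonymous`. Every entry can be overridden
#' by supplying a JSON file to [read_weight_config()].
#'
#' @return A list of class `weight_config` with elements
#'   `functional_weight` (named numeric), `category_of` (named character),
#'   `maf_cap`, `maf_weight_max`, `maf_weight_min`.
#' @examples
#' wc <- default_weight_config()
#' wc$functional_weight[["stop_gained"]]     # 100
#' wc$functional_weight[["missense_variant"]] # 5
#' @export
default_weight_config <- function() {
  functional_weight <- c(
    stop_gained             = 100,
    frameshift_variant      = 100,
    splice_donor_variant    = 100,
    splice_acceptor_variant = 100,
    missense_variant        = 5,
    inframe_insertion       = 5,
    inframe_deletion        = 5,
    splice_region_variant   = 3,
    synonymous_variant      = 1,
    intron_variant          = 1,
    `5_prime_UTR_variant`   = 1,
    `3_prime_UTR_variant`   = 1
  )
  category_of <- c(
    stop_gained             = "LOF",
    frameshift_variant      = "LOF",
    splice_donor_variant    = "LOF",
    splice_acceptor_variant = "LOF",
    missense_variant        = "protein_altering",
    inframe_insertion       = "protein_altering",
    inframe_deletion        = "protein_altering",
    splice_region_variant   = "splice_site",
    synonymous_variant      = "synonymous",
    intron_variant          = "intronic",
    `5_prime_UTR_variant`   = "intronic",
    `3_prime_UTR_variant`   = "intronic"
  )
  validate_weight_config(structure(
    list(
      functional_weight = functional_weight,
      category_of       = category_of,
      maf_cap           = 0.01,
      maf_weight_max    = 10,
      maf_weight_min    = 1
    ),
    class = "weight_config"
  ))
}

#' Read a weight configuration from JSON
#'
#' The file must contain an object with fields `functional_weight`
#' (consequence -> number) and `category_of` (consequence -> category label);
#' `maf_cap`, `maf_weight_max` and `maf_weight_min` are optional and default
#' to 0.01, 10 and 1.
#'
#' @param path Path to a JSON file.
#' @return A validated `weight_config`.
#' @export
read_weight_config <- function(path) {
  if (!file.exists(path)) stop("weight config not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  wc <- structure(
    list(
      functional_weight = unlist(raw$functional_weight),
      category_of       = unlist(raw$category_of),
      maf_cap           = raw$maf_cap %||% 0.01,
      maf_weight_max    = raw$maf_weight_max %||% 10,
      maf_weight_min    = raw$maf_weight_min %||% 1
    ),
    class = "weight_config"
  )
  validate_weight_config(wc)
}

validate_weight_config <- function(wc) {
  fw <- wc$functional_weight
  if (is.null(names(fw)) || any(!nzchar(names(fw))))
    stop("functional_weight must be a named map consequence -> weight")
  if (any(!is.finite(fw)) || any(fw <= 0))
    stop("functional weights must be positive numbers")
  missing_cat <- setdiff(names(fw), names(wc$category_of))
  if (length(missing_cat))
    stop("consequence terms lack a category: ",
         paste(missing_cat, collapse = ", "))
  if (!(wc$maf_weight_min <= wc$maf_weight_max))
    stop("maf_weight_min must be <= maf_weight_max")
  if (!(wc$maf_cap > 0 && wc$maf_cap <= 0.5))
    stop("maf_cap must lie in (0, 0.5]")
  wc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Functional weight of a consequence term
#'
#' @param consequence Character vector of consequence terms.
#' @param weight_config A `weight_config`; defaults to
#'   [default_weight_config()].
#' @return Numeric vector of weights.
#' @examples
#' assign_functional_weight(c("stop_gained", "missense_variant"))
#' @export
assign_functional_weight <- function(consequence,
                                     weight_config = default_weight_config()) {
  unknown <- setdiff(unique(consequence), names(weight_config$functional_weight))
  if (length(unknown))
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "))
  unname(weight_config$functional_weight[consequence])
}

#' Category of a consequence term
#'
#' @inheritParams assign_functional_weight
#' @return Character vector of category labels.
#' @export
variant_category <- function(consequence,
                             weight_config = default_weight_config()) {
  unknown <- setdiff(unique(consequence), names(weight_config$category_of))
  if (length(unknown))
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "))
  unname(weight_config$category_of[consequence])
}

#' Minor-allele-frequency weight
#'
#' Linear interpolation between `maf_weight_max` at MAF = 0 and
#' `maf_weight_min` at MAF = `maf_cap`:
#' `w = min + (max - min) * (cap - maf) / cap`.
#' With the defaults this gives weight 10 to variants with MAF close to zero
#' and weight 1 at MAF = 0.01.
#'
#' @param maf Numeric vector of minor allele frequencies in
#'   `[0, maf_cap]`.
#' @inheritParams assign_functional_weight
#' @return Numeric vector of weights in `[maf_weight_min, maf_weight_max]`.
#' @examples
#' maf_weight(c(0, 0.005, 0.01))  # 10, 5.5, 1
#' @export
maf_weight <- function(maf, weight_config = default_weight_config()) {
  wc <- weight_config
  if (any(!is.finite(maf)) || any(maf < 0))
    stop("maf must be finite and non-negative")
  if (any(maf > wc$maf_cap + 1e-12))
    stop("maf exceeds maf_cap (", wc$maf_cap,
         "); such variants should have been filtered out")
  wc$maf_weight_min +
    (wc$maf_weight_max - wc$maf_weight_min) * (wc$maf_cap - pmin(maf, wc$maf_cap)) / wc$maf_cap
}

#' @export
print.weight_config <- function(x, ...) {
  cat("<weight_config>\n")
  cat("  consequences:", length(x$functional_weight), "\n")
  cat("  categories:  ", paste(sort(unique(x$category_of)), collapse = ", "), "\n")
  cat(sprintf("  MAF weight:   %g at MAF=0 -> %g at MAF=%g\n",
              x$maf_weight_max, x$maf_weight_min, x$maf_cap))
  invisible(x)
}
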