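# Learnable-parameter accounting. Counts cover convolution/FC weights and
# biases plus the two per-channel affine terms of each normalization layer;
# batch-normalization running statistics are not learnable and are excluded.

# Closed-form per-layer counts derived from the architecture.
closed_form_counts <- function(cfg) {
  w <- model_widths(cfg)
  S <- cfg$scales; F1 <- cfg$F1; D <- cfg$D; F2 <- cfg$F2; F3 <- cfg$F3
  data.frame(
    block = c("pre", "pre", "spatial",
              "multiscale", "multiscale", "multiscale",
              "highlevel", "highlevel", "highlevel", "highlevel", "highlevel",
              "classifier"),
    layer = c("sconv_right", "sconv_left", "sconv",
              paste0("dtconv_s", 1:3),
              "dtconv_1", "pconv_1", "dtconv_2", "pconv_2", "skip_pconv",
              "fc"),
    count = c(cfg$m_r + 1L, cfg$m_l + 1L,
              2L * F1 + F1 + 2L * F1,
              F1 * D * S[1] + F1 * D + 2L * F1 * D,
              F1 * D * S[2] + F1 * D + 2L * F1 * D,
              F1 * D * S[3] + F1 * D + 2L * F1 * D,
              w$Cm * D * S[3] + w$CmD + 2L * w$CmD,
              F3 * w$CmD + F3 + 2L * F3,
              F3 * D * S[3] + w$F3D + 2L * w$F3D,
              F2 * w$F3D + F2 + 2L * F2,
              F2 * w$Cm + F2,
              2L * F2 + 2L),
    stringsAsFactors = FALSE
  )
}

# Exhaustive enumeration of the built model's parameter containers, grouped
# into the same layers as the closed forms.
enumerate_counts <- function(model) {
  p <- model$params
  n <- function(...) sum(vapply(list(...), length, integer(1)))
  c(sconv_right = n(p$pre_r_w, p$pre_r_b),
    sconv_left = n(p$pre_l_w, p$pre_l_b),
    sconv = n(p$fs_w, p$fs_b, p$fs_g, p$fs_be),
    dtconv_s1 = n(p$ms1_w, p$ms1_b, p$ms1_g, p$ms1_be),
    dtconv_s2 = n(p$ms2_w, p$ms2_b, p$ms2_g, p$ms2_be),
    dtconv_s3 = n(p$ms3_w, p$ms3_b, p$ms3_g, p$ms3_be),
    dtconv_1 = n(p$h1_w, p$h1_b, p$h1_g, p$h1_be),
    pconv_1 = n(p$p1_w, p$p1_b, p$p1_g, p$p1_be),
    dtconv_2 = n(p$h2_w, p$h2_b, p$h2_g, p$h2_be),
    pconv_2 = n(p$p2_w, p$p2_b, p$p2_g, p$p2_be),
    skip_pconv = n(p$skip_w, p$skip_b),
    fc = n(p$fc_w, p$fc_b))
}

#' Per-layer learnable-parameter report
#'
#' Counts the learnable parameters of every layer twice -- once from the
#' architectural closed forms and once by exhaustively enumerating the built
#' model's parameter arrays -- and errors if the two disagree.
#'
#' @param model A `mseegnet` model.
#' @return A data frame of class `mseegnet_params` with columns `block`,
#'   `layer`, `count`; the total is available via `sum(.$count)` or
#'   [total_parameters()].
#' @examples
#' count_parameters(mseegnet(mseegnet_config()))
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mseegnet"))
  rep <- closed_form_counts(model$config)
  enum <- enumerate_counts(model)
  if (!identical(as.integer(rep$count), as.integer(unname(enum[rep$layer])))) {
    stop("internal consistency error: closed-form and enumerated parameter ",
         "counts disagree", call. = FALSE)
  }
  class(rep) <- c("mseegnet_params", "data.frame")
  rep
}

#' Total learnable-parameter count
#' @param model A `mseegnet` model.
#' @return Integer total.
#' @export
total_parameters <- function(model) {
  sum(count_parameters(model)$count)
}

#' @export
print.mseegnet_params <- function(x, ...) {
  cat("Learnable parameters\n")
  df <- as.data.frame(x)
  df$count <- format(df$count, big.mark = ",")
  print(df, row.names = FALSE, right = FALSE)
  cat(sprintf("total: %s\n", format(sum(x$count), big.mark = ",")))
  invisible(x)
}
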