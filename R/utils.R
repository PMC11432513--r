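#' @keywords internal
"_PACKAGE"

#' @importFrom stats hclust cutree cmdscale as.dist sd setNames
#' @importFrom utils read.delim write.table combn
NULL

UNAMBIG <- c("A", "C", "G", "T")

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is half-to-even).
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# TRUE for positions holding an unambiguous base.
is_unambiguous <- function(x) x %in% UNAMBIG

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "barcodelim_error")))
}
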