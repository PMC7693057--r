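#' @importFrom rlang %||% abort warn .data
#' @importFrom stats quantile rnorm rbinom runif rlnorm setNames plogis qlogis
#' @importFrom utils head tail
NULL

clamp01 <- function(x) pmin(1, pmax(0, x))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

geomean <- function(x) exp(mean(log(x)))

# linear-interpolation empirical quantile (stats type 7); fixed so that
# Monte-Carlo envelopes are bit-reproducible across platforms
quantile7 <- function(x, probs) unname(stats::quantile(x, probs, type = 7, names = FALSE))

endpoint_classes <- c("survival", "reproduction", "abundance", "population_growth")

# endpoint classes whose raw data arrive as fraction-of-control rather than
# fraction affected; stored internally as 1 - fraction-of-control
inverted_classes <- c("abundance", "population_growth")
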