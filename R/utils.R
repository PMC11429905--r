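#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx aov dnorm kruskal.test median p.adjust plogis pnorm
#'   predict qnorm quantile rbinom rlnorm rnorm runif sd shapiro.test var
#'   TukeyHSD IQR setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Lightweight structured logging: every validation / guard action funnels
# through here so callers can silence or sink it.
utfmp_log <- function(module, msg) {
  message(sprintf("[utfmp:%s] %s", module, msg))
}

# Deterministic child-seed derivation. Keeps all seeds below 2^31 and makes
# every source of randomness a pure function of the base seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647)
}

# Run expr with a local RNG state so package internals never disturb the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

GROUP_LEVELS <- c("control", "benign", "malignant")

STRIP_PARAMS <- c("leukocytes", "nitrite", "pH", "specific_gravity", "protein",
                  "glucose", "ketones", "urobilinogen", "bilirubin", "blood")
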