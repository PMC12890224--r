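# Internal neural-network plumbing: activations, initialization, softmax.

.activation <- function(name) {
  switch(name,
    relu = list(f = function(x) pmax(x, 0), df = function(x) (x > 0) * 1),
    tanh = list(f = base::tanh, df = function(x) 1 - base::tanh(x)^2),
    linear = list(f = identity, df = function(x) array(1, dim = dim(x))),
    stop("unknown activation: ", name)
  )
}

.attn_divisor <- function(d, scale) {
  switch(scale, dim = d, sqrt_dim = sqrt(d),
         stop("attention_scale must be 'dim' or 'sqrt_dim'"))
}

# Scaled uniform fan-in initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
.init_weight <- function(fan_in, fan_out) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Row softmax with max-subtraction; optional multiplicative non-negative
# bias B restricted to a logical support mask (bias entries on the support
# must be strictly positive so every row keeps positive mass).
.masked_softmax <- function(S, B = NULL, support = NULL) {
  if (!is.null(support)) S[!support] <- -Inf
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  if (!is.null(B)) E <- E * B
  if (!is.null(support)) E[!support] <- 0
  E / rowSums(E)
}
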