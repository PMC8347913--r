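#' Dilated-convolution network specification
#'
#' Describes one member of the regression network family: three
#' convolutional blocks, block `i` holding `C[i]` convolution layers with
#' square `K[i] x K[i]` kernels at dilation rate `D[i]` ("same" zero
#' padding, ReLU), each block followed by a 2x2 max-pool; then a flatten
#' and a linear head with 2 outputs, the full major and minor pupil axis
#' lengths in pixels. The filter count is shared by every convolution
#' layer (32 in the reference family; configurable).
#'
#' The effective kernel extent (field of view) of block `i` is
#' `K[i] + (K[i] - 1) * (D[i] - 1)`; dilation widens the field of view
#' without adding parameters.
#'
#' @param K Integer triple of kernel sizes per block.
#' @param C Integer triple: convolution layers per block.
#' @param D Integer triple: dilation rates per block.
#' @param filters Filters per convolution layer.
#' @param input_size Input image side in pixels (square, grayscale).
#' @param hidden_units Optional hidden dense layer size before the 2-output
#'   head (0 = plain linear head).
#' @return Object of class `"network_spec"`.
#' @seealso [pupilnet_presets()] for the nine named family members.
#' @export
network_spec <- function(K = c(3, 3, 3), C = c(1, 1, 1), D = c(1, 1, 1),
                         filters = 32, input_size = 152, hidden_units = 0) {
  chk <- function(v, nm) {
    if (length(v) != 3 || any(v != as.integer(v)) || any(v < 1))
      config_error("%s must be a triple of positive integers", nm)
    as.integer(v)
  }
  K <- chk(K, "K"); C <- chk(C, "C"); D <- chk(D, "D")
  if (filters < 1 || input_size < 8)
    config_error("filters must be >= 1 and input_size >= 8")
  spec <- structure(list(K = K, C = C, D = D,
                         filters = as.integer(filters),
                         input_size = as.integer(input_size),
                         hidden_units = as.integer(hidden_units)),
                    class = "network_spec")
  feature_map_sizes(spec)  # validates kernel extents against map sizes
  spec
}

#' Named presets of the network family
#'
#' The nine family members span three depths (shallow `C(1,1,1)`, middle
#' `C(4,2,1)`, deep `C(8,4,2)`) and three filter types: Type I regular
#' `K(3,3,3) D(1,1,1)`, Type II dilated `K(3,3,3) D(3,2,1)`, and Type III
#' regular with the same fields of view as Type II, `K(7,5,3) D(1,1,1)`.
#'
#' @return Data frame with columns `name`, `depth`, `type`.
#' @export
pupilnet_presets <- function() {
  data.frame(
    name = c("K333_C111_D111", "K333_C111_D321", "K753_C111_D111",
             "K333_C421_D111", "K333_C421_D321", "K753_C421_D111",
             "K333_C842_D111", "K333_C842_D321", "K753_C842_D111"),
    depth = rep(c("shallow", "middle", "deep"), each = 3),
    type = rep(c("I", "II", "III"), times = 3),
    stringsAsFactors = FALSE)
}

#' Build a [network_spec()] from a preset name
#'
#' Preset names encode the triples, e.g. `"K333_C421_D321"` is
#' `K = (3,3,3)`, `C = (4,2,1)`, `D = (3,2,1)`.
#'
#' @param name Preset name.
#' @param ... Passed to [network_spec()] (`filters`, `input_size`, ...).
#' @export
network_preset <- function(name, ...) {
  m <- regmatches(name, regexec("^K(\\d)(\\d)(\\d)_C(\\d)(\\d)(\\d)_D(\\d)(\\d)(\\d)$",
                                name))[[1]]
  if (length(m) != 10)
    config_error("unrecognized preset name '%s' (expected e.g. K333_C111_D111)",
                 name)
  v <- as.integer(m[-1])
  network_spec(K = v[1:3], C = v[4:6], D = v[7:9], ...)
}

#' Effective field of view of a dilated kernel
#'
#' A `k x k` kernel at dilation rate `d` spans
#' `k + (k - 1) * (d - 1)` pixels; dilation enlarges the field of view
#' without increasing the number of parameters.
#'
#' @param k Kernel size (>= 1).
#' @param d Dilation rate (>= 1).
#' @return Extent in pixels (vectorized over `k`, `d`).
#' @export
effective_fov <- function(k, d) {
  if (any(k < 1) || any(d < 1)) config_error("k and d must be >= 1")
  k + (k - 1) * (d - 1)
}

#' Feature-map sizes through the network
#'
#' @param spec A [network_spec()].
#' @return Integer vector of map sizes: input, then after each of the three
#'   pooling stages (floor division by 2).
#' @export
feature_map_sizes <- function(spec) {
  s <- spec$input_size
  sizes <- s
  for (i in 1:3) {
    ke <- effective_fov(spec$K[i], spec$D[i])
    if (ke > s)
      config_error("block %d effective kernel extent (%d) exceeds its %dx%d feature map",
                   i, ke, s, s)
    s <- s %/% 2L
    sizes <- c(sizes, s)
  }
  sizes
}

#' Number of trainable parameters
#'
#' For a [network_spec()] the count is computed analytically:
#' `(k^2 * c_in + 1) * filters` per convolution layer plus the dense head;
#' for a fitted [pupilnet()] the stored weight arrays are counted. The
#' count is independent of the dilation rates.
#'
#' @param x A `network_spec` or `pupilnet` object.
#' @param ... Unused.
#' @return Integer parameter count.
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.network_spec <- function(x, ...) {
  total <- 0
  cin <- 1L
  for (i in 1:3) for (j in seq_len(x$C[i])) {
    total <- total + (x$K[i]^2 * cin + 1) * x$filters
    cin <- x$filters
  }
  flat <- feature_map_sizes(x)[4]^2 * x$filters
  if (x$hidden_units > 0) {
    total <- total + (flat + 1) * x$hidden_units
    flat <- x$hidden_units
  }
  total + (flat + 1) * 2
}

#' @export
count_parameters.pupilnet <- function(x, ...) {
  sum(vapply(x$weights, function(p) length(p$w) + length(p$b), numeric(1)))
}

# Deterministic weight initialization: He-normal for the ReLU convolutions,
# Glorot-uniform for the dense layers. Returns a flat list of layer
# records: list(kind, w, b, k, d, pad) in forward order.
init_network <- function(spec, seed = NULL) {
  with_preserved_seed(seed, {
    layers <- list()
    cin <- 1L
    for (i in 1:3) {
      for (j in seq_len(spec$C[i])) {
        k <- spec$K[i]
        w <- array(rnorm(k * k * cin * spec$filters, sd = sqrt(2 / (k * k * cin))),
                   dim = c(k, k, cin, spec$filters))
        layers[[length(layers) + 1]] <-
          list(kind = "conv", w = w, b = numeric(spec$filters),
               k = k, d = spec$D[i], pad = ((k - 1L) * spec$D[i]) %/% 2L,
               block = i)
        cin <- spec$filters
      }
      layers[[length(layers) + 1]] <- list(kind = "pool", w = numeric(0),
                                           b = numeric(0))
    }
    flat <- feature_map_sizes(spec)[4]^2 * spec$filters
    if (spec$hidden_units > 0) {
      lim <- sqrt(6 / (flat + spec$hidden_units))
      layers[[length(layers) + 1]] <-
        list(kind = "dense", w = matrix(runif(spec$hidden_units * flat, -lim, lim),
                                        spec$hidden_units, flat),
             b = numeric(spec$hidden_units), relu = TRUE)
      flat <- spec$hidden_units
    }
    lim <- sqrt(6 / (flat + 2))
    layers[[length(layers) + 1]] <-
      list(kind = "dense", w = matrix(runif(2 * flat, -lim, lim), 2, flat),
           b = numeric(2), relu = FALSE)
    layers
  })
}
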