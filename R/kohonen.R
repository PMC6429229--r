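# Kohonen self-organizing map core. The same training loop drives the
# unsupervised uses (descriptor-similarity reduction, coverage-preserving
# splitting) and, with an output layer attached, the counter-propagation
# network in cpann.R.
#
# Conventions: neurons are indexed row-major on a rows x cols grid;
# neighbourhoods are square (Chebyshev grid distance) with a triangular
# weight a = 1 - d/(r+1); the radius shrinks linearly from the full grid
# radius to 0 (winner-only) and the learning rate decays linearly from
# eta_max to eta_min over epochs. Callers are responsible for seeding.

grid_distances <- function(rows, cols) {
  rr <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)
  pmax(abs(outer(rr, rr, "-")), abs(outer(cc, cc, "-")))
}

# Winner = neuron minimizing Euclidean distance; which.min breaks ties at
# the lowest row-major index.
winner_of <- function(w, xi) {
  d2 <- rowSums(sweep(w, 2, xi)^2)
  j <- which.min(d2)
  list(index = j, distance = sqrt(d2[j]))
}

kohonen_train <- function(x, y = NULL, rows, cols, epochs,
                          eta_max = 0.5, eta_min = 0.01) {
  n <- nrow(x)
  m <- ncol(x)
  n_neurons <- rows * cols
  if (n == 0L) abort("empty training set")
  if (any(!is.finite(x))) abort("non-finite descriptor values")

  gd <- grid_distances(rows, cols)
  w <- matrix(runif(n_neurons * m, -0.5, 0.5), n_neurons, m)
  colnames(w) <- colnames(x)
  u <- NULL
  if (!is.null(y)) {
    y <- as.matrix(y)
    u <- matrix(runif(n_neurons * ncol(y), min(y), max(y)),
                n_neurons, ncol(y))
  }

  r_max <- max(rows, cols) - 1L
  for (t in seq_len(epochs)) {
    frac <- if (epochs > 1L) (t - 1) / (epochs - 1) else 1
    eta <- eta_max + (eta_min - eta_max) * frac
    radius <- floor(r_max * (1 - frac))
    order_t <- sample.int(n)
    for (i in order_t) {
      xi <- x[i, ]
      win <- winner_of(w, xi)$index
      nb <- which(gd[win, ] <= radius)
      a <- 1 - gd[win, nb] / (radius + 1)
      w[nb, ] <- w[nb, ] + (eta * a) * (rep(xi, each = length(nb)) - w[nb, , drop = FALSE])
      if (!is.null(u)) {
        u[nb, ] <- u[nb, ] + (eta * a) * (rep(y[i, ], each = length(nb)) - u[nb, , drop = FALSE])
      }
    }
  }
  list(w = w, u = u, rows = rows, cols = cols)
}

# Unsupervised fit wrapper used by split_dataset() and kohonen_reduce().
som_fit <- function(x, rows, cols, epochs = 50L,
                    eta_max = 0.5, eta_min = 0.01) {
  fit <- kohonen_train(x, NULL, rows, cols, epochs, eta_max, eta_min)
  structure(fit, class = "som_fit")
}

# Map objects onto a fitted SOM: winning neuron and distance per row.
som_map <- function(som, x) {
  hits <- apply(x, 1L, function(xi) {
    win <- winner_of(som$w, xi)
    c(win$index, win$distance)
  })
  tibble::tibble(
    compound_id = rownames(x),
    neuron = as.integer(hits[1L, ]),
    distance = hits[2L, ]
  )
}

#' Reduce a descriptor pool by Kohonen-map similarity
#'
#' Trains a self-organizing map on the transposed descriptor matrix —
#' descriptors become the objects, described by their values across
#' compounds — so that similar descriptors land on the same neuron. For
#' each occupied neuron the single descriptor closest to the neuron's
#' weight vector is retained; the retained pool size therefore equals the
#' number of occupied neurons and is bounded by the grid size.
#'
#' @param data Standardized descriptor tibble.
#' @param grid Optional `(rows, cols)`; if absent, the smallest near-square
#'   grid with at least `target_pool` neurons is used.
#' @param target_pool Desired pool size when `grid` is absent; default 25.
#' @param seed Integer seed.
#' @param epochs Training epochs for the map; default 50.
#' @return Character vector of retained descriptor names, in input order.
#' @export
#' @examples
#' d <- simulate_qsar_dataset(qsar_spec(seed = 1))
#' pool <- kohonen_reduce(autoscale(d$descriptors), target_pool = 16, seed = 3)
kohonen_reduce <- function(data, grid = NULL, target_pool = 25L, seed = 1L,
                           epochs = 50L) {
  x <- desc_matrix(data)
  if (is.null(grid)) {
    target_pool <- check_count(target_pool, "target_pool")
    rows <- ceiling(sqrt(target_pool))
    cols <- ceiling(target_pool / rows)
    grid <- c(rows, cols)
  }
  if (prod(grid) > ncol(x)) {
    warn("SOM grid has more neurons than descriptors; result may equal input")
  }
  xt <- t(x) # descriptors as objects
  with_seed(seed, {
    som <- som_fit(xt, grid[1L], grid[2L], epochs = epochs)
    mapped <- som_map(som, xt)
    kept <- mapped |>
      dplyr::group_by(.data$neuron) |>
      dplyr::slice_min(.data$distance, n = 1L, with_ties = FALSE) |>
      dplyr::pull(.data$compound_id)
    colnames(x)[colnames(x) %in% kept]
  })
}
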