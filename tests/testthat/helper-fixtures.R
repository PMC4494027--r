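# shared fixtures and independent oracles, built in code at test time

# an ROI covering an explicit set of linear indices on a grid
fixture_roi <- function(grid_dim, lin = seq_len(prod(grid_dim)),
                        name = "fixture", voxel_size_mm = c(2, 2, 3)) {
  vox <- arrayInd(lin, grid_dim)
  structure(list(name = name, voxels = vox, size = length(lin),
                 connectivity = 26, mean_z = 0,
                 center_of_mass_mm = colMeans(vox),
                 voxel_size_mm = voxel_size_mm, grid_dim = grid_dim),
            class = "roi")
}

# simulate a subject's main-experiment sessions from an explicit signal spec
fixture_sessions <- function(n_sessions, sig, grid_dim, seed0 = 1L,
                             params = design_params(), all_guessed = TRUE) {
  evs <- lapply(seq_len(n_sessions), function(s) {
    ev <- build_session_timeline(params, seed = seed0 + s, session_id = s)
    if (all_guessed) {
      ev$subjective[ev$trial_type != "fixation"] <- "guessed"
      ev
    } else {
      simulate_awareness(ev, awareness_model(seed = seed0 + 100 + s))
    }
  })
  runs <- lapply(seq_len(n_sessions), function(s)
    simulate_bold(evs[[s]], sig, noise_spec(seed = seed0 + 200 + s), grid_dim))
  list(runs = runs, events = evs)
}

# independent oracle: all connected subsets of given size within a mask
# (breadth enumeration; only for tiny masks)
enumerate_connected_subsets <- function(mask, size, connectivity = 26) {
  d <- dim(mask)
  offs <- connectivity_offsets(connectivity)
  lin <- which(mask)
  neighbors <- lapply(lin, function(l) {
    ix <- arrayInd(l, d)
    nb <- cbind(ix[1] + offs[, 1], ix[2] + offs[, 2], ix[3] + offs[, 3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    nbl <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
    intersect(nbl, lin)
  })
  names(neighbors) <- as.character(lin)
  out <- list()
  # grow all connected sets from each start, dedupe by canonical key
  seen <- new.env(hash = TRUE)
  grow <- function(set, frontier) {
    if (length(set) == size) {
      key <- paste(sort(set), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <<- sort(set)
      }
      return(invisible())
    }
    for (v in frontier) {
      newf <- union(setdiff(frontier, v),
                    setdiff(neighbors[[as.character(v)]], c(set, v)))
      grow(c(set, v), newf)
    }
  }
  for (s in lin) grow(s, neighbors[[as.character(s)]])
  out
}

# independent BFS connectivity check
is_connected_set <- function(lin, grid_dim, connectivity = 26) {
  if (length(lin) <= 1) return(TRUE)
  mask <- array(FALSE, grid_dim); mask[lin] <- TRUE
  offs <- connectivity_offsets(connectivity)
  visited <- rep(FALSE, length(lin)); names(visited) <- as.character(sort(lin))
  queue <- sort(lin)[1]; visited[as.character(queue)] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ix <- arrayInd(v, grid_dim)
    nb <- cbind(ix[1] + offs[, 1], ix[2] + offs[, 2], ix[3] + offs[, 3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid_dim[1] &
      nb[, 2] >= 1 & nb[, 2] <= grid_dim[2] &
      nb[, 3] >= 1 & nb[, 3] <= grid_dim[3]
    nb <- nb[ok, , drop = FALSE]
    nbl <- nb[, 1] + (nb[, 2] - 1) * grid_dim[1] +
      (nb[, 3] - 1) * grid_dim[1] * grid_dim[2]
    for (u in intersect(nbl, lin)) {
      if (!visited[as.character(u)]) {
        visited[as.character(u)] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  all(visited)
}

# build block_patterns directly (bypassing the BOLD stage) for decoder tests
fixture_patterns <- function(n_sessions, blocks_per_cond, p, delta = 0,
                             seed = 1, sd = 1) {
  set.seed(seed)
  n <- n_sessions * blocks_per_cond * 2
  cond <- rep(rep(c("sentences", "nonwords"), each = blocks_per_cond),
              n_sessions)
  sess <- rep(seq_len(n_sessions), each = blocks_per_cond * 2)
  mu <- matrix(0, 2, p)
  if (p > 1) {
    mu[1, ] <- delta * scale(stats::rnorm(p))[, 1]   # zero-mean pattern
    mu[2, ] <- -mu[1, ]
  } else mu[1, 1] <- delta
  X <- mu[ifelse(cond == "sentences", 1, 2), , drop = FALSE] +
    matrix(stats::rnorm(n * p, sd = sd), n, p)
  block_patterns(X, cond, sess, rep("guessed", n))
}
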