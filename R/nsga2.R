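# NSGA-II, written from scratch: fast non-dominated sorting with constraint
# domination, crowding distance, binary tournament selection, SBX +
# polynomial mutation (continuous) or single-point crossover + bit flips
# (binary), mu+lambda elitism, and an archive accumulating the distinct
# rank-1 solutions of every generation.

#' Constraint-aware Pareto domination
#'
#' Deb's feasibility rule: a feasible solution dominates an infeasible one;
#' between two infeasible solutions the smaller total violation wins; between
#' two feasible solutions ordinary Pareto domination applies (no worse in
#' every objective, strictly better in at least one; all objectives
#' minimized).
#'
#' @param a,b Objective vectors of equal length.
#' @param violation_a,violation_b Non-negative total constraint violations.
#' @return `TRUE` iff `a` dominates `b`.
#' @export
dominates <- function(a, b, violation_a = 0, violation_b = 0) {
  stopifnot(length(a) == length(b))
  feas_a <- violation_a <= 0; feas_b <- violation_b <= 0
  if (feas_a && !feas_b) return(TRUE)
  if (!feas_a && feas_b) return(FALSE)
  if (!feas_a && !feas_b) return(violation_a < violation_b)
  all(a <= b) && any(a < b)
}

# n x n logical matrix: D[i, j] <- "i dominates j" (constraint-aware)
domination_matrix <- function(obj, violation = NULL) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  le <- matrix(TRUE, n, n); lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(obj))) {
    ok <- outer(obj[, k], obj[, k], "<=")
    le <- le & ok
    lt <- lt | outer(obj[, k], obj[, k], "<")
  }
  pareto <- le & lt
  if (is.null(violation) || all(violation <= 0)) return(pareto)
  feas <- violation <= 0
  both_feas <- outer(feas, feas, "&")
  i_only <- outer(feas, !feas, "&")
  both_infeas <- outer(!feas, !feas, "&")
  cv_lt <- outer(violation, violation, "<")
  (pareto & both_feas) | i_only | (both_infeas & cv_lt)
}

#' Fast non-dominated sorting
#'
#' Partitions a population into fronts F1, F2, ...: F1 is the set dominated
#' by no one; each later front is the non-dominated set once earlier fronts
#' are discounted.
#'
#' @param objectives Numeric matrix or data frame, one row per individual,
#'   all objectives minimized.
#' @param violation Optional non-negative constraint violations (constraint
#'   domination; see [dominates()]).
#' @return Integer vector of front ranks (1 = best).
#' @export
fast_non_dominated_sort <- function(objectives, violation = NULL) {
  obj <- as.matrix(objectives)
  n <- nrow(obj)
  if (n == 0) return(integer(0))
  D <- domination_matrix(obj, violation)
  n_dominating <- colSums(D) # how many dominate j
  rank <- integer(n)
  current <- 1L
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    front <- remaining & n_dominating == 0L
    if (!any(front)) { # numerical safety; cannot happen with a strict partial order
      front <- remaining
    }
    rank[front] <- current
    remaining[front] <- FALSE
    if (any(remaining)) {
      n_dominating <- n_dominating - colSums(D[front, , drop = FALSE])
    }
    current <- current + 1L
  }
  rank
}

#' Crowding distance within a front
#'
#' Per objective, individuals are sorted and boundary solutions get infinite
#' distance; interior solutions accumulate the normalized gap between their
#' two neighbours. Objectives with zero range are skipped. Fronts of one or
#' two individuals are all-infinite.
#'
#' @param objectives Objectives of the members of one front (matrix or data
#'   frame).
#' @return Numeric distances (possibly `Inf`), independent of row order.
#' @export
crowding_distance <- function(objectives) {
  obj <- as.matrix(objectives)
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    rng <- range(obj[, k])
    if (rng[2] - rng[1] <= 0) next
    ord <- order(obj[, k])
    d[ord[c(1, n)]] <- Inf
    gaps <- (obj[ord[3:n], k] - obj[ord[1:(n - 2)], k]) / (rng[2] - rng[1])
    d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] + gaps
  }
  d
}

#' Keep the distinct non-dominated rows of a solution set
#'
#' Removes duplicated rows, then every row dominated by another row. The
#' operation is idempotent and the result mutually non-dominated.
#'
#' @param data Data frame of solutions.
#' @param objectives Names of the (minimized) objective columns.
#' @param violation Optional name of a violation column.
#' @return The filtered data frame.
#' @export
pareto_filter <- function(data, objectives = c("obj1", "obj2", "obj3"),
                          violation = NULL) {
  data <- distinct(as_tibble(data))
  if (nrow(data) <= 1) return(data)
  cv <- if (is.null(violation)) NULL else data[[violation]]
  keep <- !apply(domination_matrix(as.matrix(data[, objectives]), cv), 2, any)
  data[keep, , drop = FALSE]
}

# --- variation operators ------------------------------------------------

# SBX spread factor from u ~ U(0,1): density 0.5*(eta+1)*b^eta on (0,1],
# 0.5*(eta+1)*b^-(eta+2) on (1,Inf) (inverse-CDF sampling)
sbx_spread <- function(u, eta) {
  ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)), (1 / (2 * (1 - u)))^(1 / (eta + 1)))
}

# simulated binary crossover on paired parent matrices; per-gene exchange
# with prob 0.5 within crossing pairs; children clipped to the box
sbx_crossover <- function(P1, P2, lower, upper, p_crossover, eta) {
  n <- nrow(P1); d <- ncol(P1)
  cross_pair <- runif(n) < p_crossover
  beta <- sbx_spread(matrix(runif(n * d), n, d), eta)
  gene <- matrix(runif(n * d), n, d) < 0.5
  do_it <- cross_pair & gene
  C1 <- ifelse(do_it, 0.5 * ((1 + beta) * P1 + (1 - beta) * P2), P1)
  C2 <- ifelse(do_it, 0.5 * ((1 - beta) * P1 + (1 + beta) * P2), P2)
  clip <- function(X) pmin(pmax(X, matrix(lower, n, d, byrow = TRUE)),
                           matrix(upper, n, d, byrow = TRUE))
  list(clip(C1), clip(C2))
}

# bounded polynomial mutation (Deb), per gene with prob p_mutation
polynomial_mutation <- function(X, lower, upper, p_mutation, eta) {
  n <- nrow(X); d <- ncol(X)
  lo <- matrix(lower, n, d, byrow = TRUE)
  up <- matrix(upper, n, d, byrow = TRUE)
  span <- up - lo
  mutate <- matrix(runif(n * d), n, d) < p_mutation
  u <- matrix(runif(n * d), n, d)
  d1 <- (X - lo) / span
  d2 <- (up - X) / span
  pow <- 1 / (eta + 1)
  deltaq <- ifelse(
    u < 0.5,
    (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^pow - 1,
    1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^pow
  )
  Y <- ifelse(mutate, X + deltaq * span, X)
  pmin(pmax(Y, lo), up)
}

# single-point crossover + independent bit flips
binary_variation <- function(P1, P2, p_crossover, p_mutation) {
  n <- nrow(P1); d <- ncol(P1)
  C1 <- P1; C2 <- P2
  if (d >= 2) {
    cross_pair <- runif(n) < p_crossover
    pts <- sample.int(d - 1L, n, replace = TRUE)
    for (i in which(cross_pair)) {
      tail_idx <- (pts[i] + 1L):d
      C1[i, tail_idx] <- P2[i, tail_idx]
      C2[i, tail_idx] <- P1[i, tail_idx]
    }
  }
  flip <- function(X) {
    mask <- matrix(runif(n * d), n, d) < p_mutation
    ifelse(mask, 1 - X, X)
  }
  list(flip(C1), flip(C2))
}

# binary tournament on (rank asc, crowding desc, coin flip)
tournament_select <- function(rank, crowding, n_pick) {
  n <- length(rank)
  i <- sample.int(n, n_pick, replace = TRUE)
  j <- sample.int(n, n_pick, replace = TRUE)
  better <- rank[i] < rank[j] |
    (rank[i] == rank[j] & crowding[i] > crowding[j]) |
    (rank[i] == rank[j] & crowding[i] == crowding[j] & runif(n_pick) < 0.5)
  ifelse(better, i, j)
}

#' NSGA-II settings
#'
#' Defaults are the published settings for this problem: population 100,
#' 250 generations, crossover probability 0.9, distribution indices 20
#' (crossover) and 10 (mutation), mutation probability 0.1 per variable for
#' continuous decisions and 0.01 per bit for binary ones.
#'
#' @param pop_size Population size N.
#' @param generations Number of generations.
#' @param p_crossover Per-pair crossover probability.
#' @param p_mutation Per-gene mutation probability; `NULL` picks 0.1
#'   (continuous) or 0.01 (binary) by problem type.
#' @param eta_crossover,eta_mutation SBX / polynomial-mutation distribution
#'   indices (continuous problems only).
#' @param constraint_mode How linkage constraints are enforced on allele
#'   problems: `"block_encoding"` optimizes one bit per haplotype block
#'   (constraints hold by construction), `"constraint_domination"` optimizes
#'   all loci and penalizes violations through the domination rule.
#' @param archive `"all_nondominated"` accumulates the distinct rank-1
#'   solutions of every generation (the default; solution counts can then
#'   exceed N), `"final_population"` reports the non-dominated subset of the
#'   last population only.
#' @param seed Optional RNG seed set at the start of the run.
#' @return A list of class `nsga_control`.
#' @export
nsga_control <- function(pop_size = 100, generations = 250, p_crossover = 0.9,
                         p_mutation = NULL, eta_crossover = 20,
                         eta_mutation = 10,
                         constraint_mode = c("block_encoding", "constraint_domination"),
                         archive = c("all_nondominated", "final_population"),
                         seed = NULL) {
  constraint_mode <- match.arg(constraint_mode)
  archive <- match.arg(archive)
  if (pop_size < 4 || pop_size %% 2 != 0) {
    abort("`pop_size` must be an even integer >= 4.")
  }
  if (generations < 1) abort("`generations` must be >= 1.")
  for (p in c("p_crossover", "p_mutation")) {
    v <- get(p)
    if (!is.null(v) && (v < 0 || v > 1)) {
      abort(sprintf("`%s` must be in [0, 1].", p))
    }
  }
  structure(
    list(
      pop_size = as.integer(pop_size), generations = as.integer(generations),
      p_crossover = p_crossover, p_mutation = p_mutation,
      eta_crossover = eta_crossover, eta_mutation = eta_mutation,
      constraint_mode = constraint_mode, archive = archive, seed = seed
    ),
    class = "nsga_control"
  )
}

#' Define an optimization problem for [nsga2()]
#'
#' @param evaluate Batch evaluation function: takes a decision matrix (one
#'   row per individual) and returns a list with `objectives` (matrix, all
#'   minimized) and optionally `violation` (non-negative vector).
#' @param n_var Number of decision variables.
#' @param type `"continuous"` (box-bounded reals) or `"binary"` (0/1 bits).
#' @param lower,upper Box bounds (continuous problems).
#' @param var_names Optional decision-column names for reporting.
#' @return A list of class `nsga_problem`.
#' @export
nsga_problem <- function(evaluate, n_var, type = c("continuous", "binary"),
                         lower = NULL, upper = NULL, var_names = NULL) {
  type <- match.arg(type)
  if (type == "continuous") {
    stopifnot(length(lower) == n_var, length(upper) == n_var, all(lower < upper))
  }
  if (is.null(var_names)) {
    var_names <- paste0(if (type == "binary") "bit" else "x", seq_len(n_var))
  }
  structure(
    list(evaluate = evaluate, n_var = as.integer(n_var), type = type,
         lower = lower, upper = upper, var_names = var_names),
    class = "nsga_problem"
  )
}

# duplicate keys: exact for binary decisions, 12 significant digits for
# continuous ones
decision_keys <- function(X, type) {
  if (type == "binary") {
    apply(X, 1, paste, collapse = "")
  } else {
    apply(signif(X, 12), 1, paste, collapse = "|")
  }
}

#' Run NSGA-II
#'
#' mu+lambda elitist loop: each generation the parent and child populations
#' are merged, sorted by constrained non-domination, and truncated back to N
#' by (rank, crowding distance). Reproducible for a fixed seed.
#'
#' @param problem An [nsga_problem()].
#' @param control An [nsga_control()].
#' @return An object of class `nsga_result` with tibbles `population` (final
#'   population with rank/crowding) and `archive` (distinct non-dominated
#'   solutions; see the `archive` control), plus the evaluation count and
#'   the control used. [tidy()] returns the archive, [glance()] a one-row
#'   summary, [autoplot()] the objective space.
#' @export
nsga2 <- function(problem, control = nsga_control()) {
  stopifnot(inherits(problem, "nsga_problem"))
  if (!is.null(control$seed)) set.seed(control$seed)
  n <- control$pop_size
  d <- problem$n_var
  pm <- control$p_mutation
  if (is.null(pm)) pm <- if (problem$type == "binary") 0.01 else 0.1

  evaluate <- function(X) {
    res <- problem$evaluate(X)
    if (is.null(res$violation)) res$violation <- numeric(nrow(X))
    stopifnot(nrow(res$objectives) == nrow(X))
    if (any(!is.finite(res$objectives))) {
      abort("Objective evaluation produced non-finite values.")
    }
    res
  }

  X <- if (problem$type == "binary") {
    matrix(as.double(runif(n * d) < 0.5), n, d)
  } else {
    matrix(runif(n * d), n, d) %*% diag(problem$upper - problem$lower, d) +
      matrix(problem$lower, n, d, byrow = TRUE)
  }
  ev <- evaluate(X)
  obj <- ev$objectives; cv <- ev$violation
  n_eval <- n

  rank <- fast_non_dominated_sort(obj, cv)
  crowd <- crowding_per_front(obj, rank)
  arch <- init_archive(X, obj, cv, rank, problem$type)

  for (gen in seq_len(control$generations)) {
    parents <- tournament_select(rank, crowd, n)
    i1 <- parents[seq(1, n, by = 2)]
    i2 <- parents[seq(2, n, by = 2)]
    if (problem$type == "binary") {
      ch <- binary_variation(X[i1, , drop = FALSE], X[i2, , drop = FALSE],
                             control$p_crossover, pm)
    } else {
      ch <- sbx_crossover(X[i1, , drop = FALSE], X[i2, , drop = FALSE],
                          problem$lower, problem$upper,
                          control$p_crossover, control$eta_crossover)
      ch <- lapply(ch, polynomial_mutation, lower = problem$lower,
                   upper = problem$upper, p_mutation = pm,
                   eta = control$eta_mutation)
    }
    Q <- rbind(ch[[1]], ch[[2]])
    evq <- evaluate(Q)
    n_eval <- n_eval + nrow(Q)

    RX <- rbind(X, Q)
    robj <- rbind(obj, evq$objectives)
    rcv <- c(cv, evq$violation)
    rrank <- fast_non_dominated_sort(robj, rcv)
    rcrowd <- crowding_per_front(robj, rrank)
    keep <- order(rrank, -rcrowd)[seq_len(n)]
    X <- RX[keep, , drop = FALSE]
    obj <- robj[keep, , drop = FALSE]
    cv <- rcv[keep]
    rank <- rrank[keep]
    crowd <- rcrowd[keep]

    if (control$archive == "all_nondominated") {
      arch <- update_archive(arch, RX, robj, rcv, rrank, problem$type)
    }
  }

  if (control$archive == "final_population") {
    arch <- init_archive(X, obj, cv, rank, problem$type)
  }

  pop <- decision_tibble(X, problem$var_names)
  pop <- bind_cols(pop, objective_tibble(obj))
  pop$violation <- cv; pop$rank <- rank; pop$crowding <- crowd
  archive <- decision_tibble(arch$X, problem$var_names)
  archive <- bind_cols(archive, objective_tibble(arch$obj))
  archive$violation <- arch$cv

  structure(
    list(population = pop, archive = archive, control = control,
         problem_type = problem$type, n_var = d, evaluations = n_eval),
    class = "nsga_result"
  )
}

crowding_per_front <- function(obj, rank) {
  crowd <- numeric(length(rank))
  for (r in unique(rank)) {
    idx <- rank == r
    crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }
  crowd
}

init_archive <- function(X, obj, cv, rank, type) {
  idx <- which(rank == 1L & cv <= 0)
  if (length(idx) == 0) idx <- which(rank == 1L)
  a <- list(X = X[idx, , drop = FALSE], obj = obj[idx, , drop = FALSE],
            cv = cv[idx])
  prune_archive(a, type)
}

update_archive <- function(arch, X, obj, cv, rank, type) {
  idx <- which(rank == 1L & cv <= 0)
  if (length(idx) == 0) return(arch)
  a <- list(X = rbind(arch$X, X[idx, , drop = FALSE]),
            obj = rbind(arch$obj, obj[idx, , drop = FALSE]),
            cv = c(arch$cv, cv[idx]))
  prune_archive(a, type)
}

# dedupe by decision vector, then keep the non-dominated subset under
# constraint domination (so infeasible entries vanish once a feasible
# solution exists)
prune_archive <- function(a, type) {
  keys <- decision_keys(a$X, type)
  first <- !duplicated(keys)
  a <- list(X = a$X[first, , drop = FALSE], obj = a$obj[first, , drop = FALSE],
            cv = a$cv[first])
  if (nrow(a$obj) > 1) {
    nd <- !apply(domination_matrix(a$obj, a$cv), 2, any)
    a <- list(X = a$X[nd, , drop = FALSE], obj = a$obj[nd, , drop = FALSE],
              cv = a$cv[nd])
  }
  a
}

decision_tibble <- function(X, var_names) {
  colnames(X) <- var_names
  as_tibble(X)
}

objective_tibble <- function(obj) {
  colnames(obj) <- paste0("obj", seq_len(ncol(obj)))
  as_tibble(obj)
}

#' @export
print.nsga_result <- function(x, ...) {
  cat("<nsga_result>", x$problem_type, "problem,", x$n_var, "variables\n")
  cat("  generations:", x$control$generations,
      " evaluations:", x$evaluations, "\n")
  cat("  archive:", nrow(x$archive), "distinct non-dominated solutions\n")
  invisible(x)
}

#' @method tidy nsga_result
#' @export
tidy.nsga_result <- function(x, ...) x$archive

#' @method glance nsga_result
#' @export
glance.nsga_result <- function(x, ...) {
  tibble(
    problem_type = x$problem_type, n_var = x$n_var,
    pop_size = x$control$pop_size, generations = x$control$generations,
    evaluations = x$evaluations, archive_size = nrow(x$archive),
    n_feasible = sum(x$archive$violation <= 0)
  )
}

#' Dominated hypervolume (minimization, 2 or 3 objectives)
#'
#' Volume of the region dominated by a point set and bounded above by a
#' reference point; the standard scalar quality indicator for Pareto fronts.
#' Points not strictly below the reference in every coordinate contribute
#' nothing.
#'
#' @param points Matrix or data frame of objective vectors (minimized).
#' @param ref Reference point (numeric, length 2 or 3).
#' @return A non-negative scalar.
#' @export
hypervolume <- function(points, ref) {
  pts <- as.matrix(points)
  m <- length(ref)
  stopifnot(ncol(pts) == m, m %in% c(2L, 3L))
  below <- rowSums(sweep(pts, 2, ref, "<")) == m
  pts <- pts[below, , drop = FALSE]
  if (nrow(pts) == 0) return(0)
  if (m == 2) return(hv2d(pts, ref))
  zs <- sort(unique(pts[, 3]))
  hv <- 0
  for (k in seq_along(zs)) {
    z_top <- if (k < length(zs)) zs[k + 1] else ref[3]
    slab <- pts[pts[, 3] <= zs[k], 1:2, drop = FALSE]
    hv <- hv + hv2d(slab, ref[1:2]) * (z_top - zs[k])
  }
  hv
}

# 2D staircase hypervolume (minimization): walking the points by increasing
# x, each new best y adds the horizontal strip [x_i, ref_x] x [y_i, best_y]
hv2d <- function(pts, ref) {
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  area <- 0
  best_y <- ref[2]
  for (i in seq_len(nrow(pts))) {
    if (pts[i, 2] < best_y) {
      area <- area + (ref[1] - pts[i, 1]) * (best_y - pts[i, 2])
      best_y <- pts[i, 2]
    }
  }
  area
}
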