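# Thin mixed-integer linear programming layer.  Models are assembled in R
# as sparse triplets and solved by the HiGHS engine behind
# scipy.optimize.milp, reached through the bundled inst/python helper.
# Batch solving amortizes interpreter startup over many small models.

#' Create an empty MILP model
#'
#' Minimal incremental model builder: variables are added with bounds,
#' integrality and objective coefficients; constraints as sparse rows with
#' lower/upper limits (use `lb == ub` for equalities).
#'
#' @return An environment of class `milp_model`.
#' @keywords internal
milp_new <- function() {
  m <- new.env(parent = emptyenv())
  m$nvar <- 0L
  m$obj <- list(); m$lb <- list(); m$ub <- list(); m$int <- list()
  m$A_i <- list(); m$A_j <- list(); m$A_x <- list()
  m$con_lb <- list(); m$con_ub <- list(); m$ncon <- 0L
  class(m) <- "milp_model"
  m
}

# Add `n` variables; returns their 1-based indices.
milp_add_vars <- function(m, n, lb = 0, ub = Inf, integer = FALSE,
                          obj = 0) {
  idx <- m$nvar + seq_len(n)
  m$nvar <- m$nvar + as.integer(n)
  m$obj[[length(m$obj) + 1L]] <- rep_len(obj, n)
  m$lb[[length(m$lb) + 1L]] <- rep_len(lb, n)
  m$ub[[length(m$ub) + 1L]] <- rep_len(ub, n)
  m$int[[length(m$int) + 1L]] <- rep_len(as.integer(integer), n)
  idx
}

# Add one linear constraint lb <= sum coef * x[ind] <= ub.
milp_add_con <- function(m, ind, coef, lb = -Inf, ub = Inf) {
  m$ncon <- m$ncon + 1L
  k <- length(m$A_i) + 1L
  m$A_i[[k]] <- rep.int(m$ncon, length(ind))
  m$A_j[[k]] <- as.integer(ind)
  m$A_x[[k]] <- as.numeric(coef)
  m$con_lb[[length(m$con_lb) + 1L]] <- lb
  m$con_ub[[length(m$con_ub) + 1L]] <- ub
  invisible(m)
}

# Add to the objective (coefficients accumulate by position).
milp_set_obj <- function(m, ind, coef) {
  obj <- unlist(m$obj, use.names = FALSE)
  obj[ind] <- obj[ind] + coef
  m$obj <- list(obj)
  invisible(m)
}

milp_payload <- function(m) {
  cap <- function(v) { v[v == Inf] <- 1e30; v[v == -Inf] <- -1e30; v }
  # I() keeps length-1 vectors as JSON arrays
  list(obj = I(unlist(m$obj, use.names = FALSE)),
       lb = I(cap(unlist(m$lb, use.names = FALSE))),
       ub = I(cap(unlist(m$ub, use.names = FALSE))),
       integrality = I(unlist(m$int, use.names = FALSE)),
       A_i = I(unlist(m$A_i, use.names = FALSE)),
       A_j = I(unlist(m$A_j, use.names = FALSE)),
       A_x = I(unlist(m$A_x, use.names = FALSE)),
       con_lb = I(cap(unlist(m$con_lb, use.names = FALSE))),
       con_ub = I(cap(unlist(m$con_ub, use.names = FALSE))))
}

milp_python <- function() {
  py <- getOption("orsched.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter found for the MILP backend; set ",
         "options(orsched.python = ...)", call. = FALSE)
  py
}

#' Solve a batch of MILP models
#'
#' @param models List of `milp_model` objects.
#' @param time_limit Per-model wall-clock limit in seconds (NULL = none).
#' @param mip_rel_gap Relative optimality gap tolerance (NULL = solver
#'   default).
#' @return A list, one element per model: `status` (`"optimal"`,
#'   `"time_limit"`, `"infeasible"`, `"unbounded"`, `"failed"`), `x`
#'   (solution vector or NULL), `objective`, `gap`.
#' @keywords internal
milp_solve_batch <- function(models, time_limit = NULL,
                             mip_rel_gap = NULL) {
  script <- system.file("python", "milp_solver.py", package = "orsched")
  if (!nzchar(script))
    stop("bundled MILP helper script not found", call. = FALSE)
  probs <- lapply(models, function(m) {
    p <- milp_payload(m)
    p$time_limit <- time_limit
    p$mip_rel_gap <- mip_rel_gap
    p
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(list(problems = probs), fin, auto_unbox = TRUE,
                       digits = NA, null = "null")
  code <- system2(milp_python(), c(script, fin, fout),
                  stdout = FALSE, stderr = "")
  if (code != 0 || !file.exists(fout))
    stop("MILP backend failed (exit code ", code, ")", call. = FALSE)
  out <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(out$results, function(r) {
    status <- switch(as.character(r$status),
                     "0" = "optimal", "1" = "time_limit",
                     "2" = "infeasible", "3" = "unbounded", "failed")
    list(status = status,
         x = if (!is.null(r$x)) as.numeric(unlist(r$x)) else NULL,
         objective = if (!is.null(r$objective)) r$objective else NA_real_,
         gap = if (!is.null(r$mip_gap)) r$mip_gap else NA_real_,
         dual_bound = if (!is.null(r$dual_bound)) r$dual_bound
                      else NA_real_)
  })
}

milp_solve <- function(model, time_limit = NULL, mip_rel_gap = NULL) {
  milp_solve_batch(list(model), time_limit, mip_rel_gap)[[1]]
}

#' Is the MILP backend available?
#'
#' Checks that a python interpreter with scipy's HiGHS interface can be
#' invoked.  Result is cached for the session.
#' @return Logical.
#' @export
milp_available <- function() {
  cached <- getOption("orsched.milp_ok", NULL)
  if (!is.null(cached)) return(cached)
  ok <- tryCatch({
    m <- milp_new()
    x <- milp_add_vars(m, 2, lb = 0, ub = 10, integer = TRUE, obj = c(-1, -2))
    milp_add_con(m, x, c(1, 1), ub = 3)
    r <- milp_solve(m)
    identical(r$status, "optimal") && abs(r$objective + 6) < 1e-8
  }, error = function(e) FALSE)
  options(orsched.milp_ok = ok)
  ok
}
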