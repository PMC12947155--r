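#' Serialize haematocrit models to and from JSON
#'
#' Models round-trip through JSON with full coefficient precision
#' (`digits = NA`), so published coefficients survive bit-exact. A linear
#' model serializes as
#' `{label, slope, intercept, n_fit, r_squared}`; a stratified model as an
#' ordered `routes` array of
#' `{predicate: {sex, bmi_low, bmi_high}, model: {...}}` plus a `fallback`
#' field. Unbounded BMI limits are stored as the strings `"-Inf"`/`"Inf"`.
#'
#' @param model A [linear_hct_model()] or [stratified_hct_model()].
#' @param path File path to write to / read from.
#' @return `write_hct_model()` returns `path` invisibly; `read_hct_model()`
#'   returns the deserialized model.
#' @export
write_hct_model <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_hct_model
#' @export
read_hct_model <- function(path) {
  model_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

model_to_list <- function(model) {
  if (inherits(model, "linear_hct_model")) {
    list(type = "linear", label = model$label, slope = model$slope,
         intercept = model$intercept, n_fit = model$n_fit,
         r_squared = if (is.na(model$r_squared)) NULL else model$r_squared)
  } else if (inherits(model, "stratified_hct_model")) {
    list(
      type = "stratified", label = model$label, fallback = model$fallback,
      routes = purrr::map(model$routes, function(r) {
        p <- r[[1]]
        list(predicate = list(sex = p$sex,
                              bmi_low = num_out(p$bmi_low),
                              bmi_high = num_out(p$bmi_high)),
             model = model_to_list(r[[2]]))
      })
    )
  } else {
    stop("Not a haematocrit model.", call. = FALSE)
  }
}

model_from_list <- function(x) {
  if (identical(x$type, "linear")) {
    linear_hct_model(x$slope, x$intercept, label = x$label %||% "",
                     n_fit = x$n_fit %||% 0L,
                     r_squared = x$r_squared %||% NA_real_)
  } else if (identical(x$type, "stratified")) {
    routes <- purrr::map(x$routes, function(r) {
      p <- r$predicate
      list(model_predicate(p$sex, num_in(p$bmi_low), num_in(p$bmi_high)),
           model_from_list(r$model))
    })
    stratified_hct_model(routes, fallback = x$fallback,
                         label = x$label %||% "stratified")
  } else {
    stop("Unrecognized model JSON.", call. = FALSE)
  }
}

# JSON has no +/-Inf; encode unbounded limits as strings
num_out <- function(x) if (is.finite(x)) x else as.character(x)
num_in <- function(x) if (is.character(x)) as.numeric(x) else x

`%||%` <- function(a, b) if (is.null(a)) b else a
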