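## Architecture descriptors and exact parameter / multiply-accumulate
## accounting.
##
## A descriptor is a flat list of parameterised layers, each annotated with
## the cumulative downsampling factor of its input ("scale", a power of 2),
## so spatial sizes -- and therefore MACs -- can be recovered for any input
## resolution. All supported topologies downsample by standard
## stride-2 / pad k%/%2 layers, for which every halving maps H -> ceil(H/2).

L_conv <- function(kh, kw, cin, cout, stride = 1L, groups = 1L,
                   bias = FALSE, scale = 1L, spatial = "map") {
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       stride = stride, groups = groups, bias = bias, scale = scale,
       spatial = spatial)
}
L_bn <- function(c) list(type = "bn", c = c)
L_linear <- function(nin, nout, bias = TRUE) {
  list(type = "linear", nin = nin, nout = nout, bias = bias)
}

spatial_at <- function(h, scale) {
  while (scale > 1) {
    h <- ceiling(h / 2)
    scale <- scale / 2
  }
  h
}

layer_params <- function(l) {
  switch(l$type,
    conv = l$kh * l$kw * (l$cin %/% l$groups) * l$cout +
      if (l$bias) l$cout else 0L,
    bn = 2L * l$c,
    linear = l$nin * l$nout + if (l$bias) l$nout else 0L,
    0L)
}

layer_macs <- function(l, input_hw) {
  switch(l$type,
    conv = {
      hw_out <- if (identical(l$spatial, "vector")) 1L
        else spatial_at(input_hw, l$scale * l$stride)
      l$kh * l$kw * (l$cin %/% l$groups) * l$cout * hw_out^2
    },
    linear = l$nin * l$nout,
    0)
}

#' Count trainable parameters of a classifier, segmentor or detector
#'
#' Counts every trainable scalar: convolution and linear weights and biases,
#' and the affine (gamma, beta) terms of batch normalisation. Running
#' batch-norm statistics are not trainable and are excluded, matching the
#' usual convention under which ResNet-34 has about 21.3 M parameters.
#'
#' @param model a model built by [build_student()], [build_teacher()],
#'   [build_segmentor()] or [build_detector()], or a bare descriptor.
#' @return integer (double for > 2^31) count of trainable scalars.
#' @export
count_parameters <- function(model) {
  if (is.list(model) && is.null(model$descriptor) && is.null(model$layers) &&
      !is.null(model$module)) {
    return(module_param_count(model$module))
  }
  layers <- arch_layers(model)
  sum(vapply(layers, layer_params, numeric(1)))
}

## Exact count over an instantiated module's parameter arrays.
module_param_count <- function(module) {
  sum(vapply(module$params, function(p) length(p$value), numeric(1)))
}

#' Count multiply-accumulate operations for one forward pass
#'
#' One MAC is counted per multiply in every convolution and linear layer
#' (the common convention under which ResNet-34 at 224x224 costs about
#' 3.7 G); pooling, activations and batch normalisation are excluded.
#'
#' @param model a built model or descriptor.
#' @param input_hw input height/width in pixels (square input).
#' @return total MAC count (double).
#' @export
count_macs <- function(model, input_hw = 224L) {
  layers <- arch_layers(model)
  bad <- vapply(layers, function(l)
    !(l$type %in% c("conv", "bn", "linear")), logical(1))
  if (any(bad)) {
    stop("unsupported layer type(s) for MAC counting: ",
         paste(unique(vapply(layers[bad], `[[`, "", "type")), collapse = ", "))
  }
  sum(vapply(layers, layer_macs, numeric(1), input_hw = input_hw))
}

arch_layers <- function(model) {
  if (!is.null(model$descriptor)) model$descriptor$layers
  else if (!is.null(model$layers)) model$layers
  else stop("not a recognised model or architecture descriptor")
}

## ---- ResNet (basic-block) descriptor --------------------------------------

arch_resnet <- function(num_classes, width = 64L, blocks = c(3L, 4L, 6L, 3L),
                        in_ch = 3L) {
  layers <- list(
    L_conv(7L, 7L, in_ch, width, stride = 2L, scale = 1L),
    L_bn(width))
  scale <- 4L # stem conv (x2) + max pool (x2)
  inplanes <- width
  for (s in seq_along(blocks)) {
    planes <- width * 2L^(s - 1L)
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      layers <- c(layers, list(
        L_conv(3L, 3L, inplanes, planes, stride = stride, scale = scale),
        L_bn(planes),
        L_conv(3L, 3L, planes, planes, scale = scale * stride),
        L_bn(planes)))
      if (stride != 1L || inplanes != planes) {
        layers <- c(layers, list(
          L_conv(1L, 1L, inplanes, planes, stride = stride, scale = scale),
          L_bn(planes)))
      }
      inplanes <- planes
      scale <- scale * stride
    }
  }
  layers <- c(layers, list(L_linear(inplanes, num_classes)))
  structure(list(name = "resnet34", layers = layers, width = width,
                 blocks = blocks, num_classes = num_classes),
            class = "echoasd_arch")
}

## ---- ResNeSt (split-attention bottleneck) descriptor ----------------------

arch_resnest <- function(num_classes, width = 64L,
                         blocks = c(3L, 24L, 36L, 3L), stem_width = 64L,
                         radix = 2L, reduction = 4L, in_ch = 3L) {
  layers <- list(
    L_conv(3L, 3L, in_ch, stem_width, stride = 2L, scale = 1L),
    L_bn(stem_width),
    L_conv(3L, 3L, stem_width, stem_width, scale = 2L),
    L_bn(stem_width),
    L_conv(3L, 3L, stem_width, stem_width * 2L, scale = 2L),
    L_bn(stem_width * 2L))
  scale <- 4L
  inplanes <- stem_width * 2L
  expansion <- 4L
  for (s in seq_along(blocks)) {
    planes <- width * 2L^(s - 1L)
    gw <- planes # cardinality 1, bottleneck width 64
    inter <- max((gw * radix) %/% reduction, 32L)
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      layers <- c(layers, list(
        L_conv(1L, 1L, inplanes, gw, scale = scale),
        L_bn(gw),
        # split-attention 3x3 (stride folded into the avg-down pool)
        L_conv(3L, 3L, gw, gw * radix, groups = radix, scale = scale),
        L_bn(gw * radix),
        L_conv(1L, 1L, gw, inter, bias = TRUE, spatial = "vector"),
        L_bn(inter),
        L_conv(1L, 1L, inter, gw * radix, bias = TRUE, spatial = "vector"),
        L_conv(1L, 1L, gw, planes * expansion, scale = scale * stride),
        L_bn(planes * expansion)))
      if (stride != 1L || inplanes != planes * expansion) {
        layers <- c(layers, list(
          L_conv(1L, 1L, inplanes, planes * expansion,
                 scale = scale * stride),
          L_bn(planes * expansion)))
      }
      inplanes <- planes * expansion
      scale <- scale * stride
    }
  }
  layers <- c(layers, list(L_linear(inplanes, num_classes)))
  structure(list(name = "resnest", layers = layers, width = width,
                 blocks = blocks, stem_width = stem_width, radix = radix,
                 num_classes = num_classes),
            class = "echoasd_arch")
}
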