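# The three-branch fusion convolutional classifier and its balanced
# training protocol.

#' Configuration of the fusion network
#'
#' Defaults reproduce the reference architecture and training protocol:
#' two convolutional blocks per image branch (each block is batch-norm,
#' padded convolution, dropout, 2x2 max-pool, ReLU), a three-layer 1-D
#' convolutional lifetime branch with kernels 7/5/3, per-branch
#' fully-connected reduction to 50 features, log-softmax output, negative
#' log-likelihood loss, and SGD with learning rate 0.001 and momentum 0.9 on
#' balanced batches of \code{perClassBatch} samples per class.
#'
#' @param nClasses number of output classes.
#' @param scatteringChannels channels of the two scattering conv layers.
#' @param spectrumChannels channels of the two spectrum conv layers.
#' @param lifetimeChannels channels of the three lifetime conv layers.
#' @param lifetimeKernels 1-D kernel sizes of the lifetime branch.
#' @param perModalityReduced width of each branch's reduction layer.
#' @param dropoutRate dropout probability after every convolution.
#' @param learningRate,momentum SGD hyper-parameters.
#' @param perClassBatch samples per class in every balanced batch.
#' @param maxEpochs epoch cap.
#' @param trainPerClass training samples drawn per class.
#' @param validationFraction fraction of the training set held out for
#'   validation-based early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed controlling initialization, splits, batch order
#'   and dropout.
#' @param expectedFlatten named flatten sizes each branch must reach; the
#'   builder errors (naming the branch) if the shape arithmetic disagrees.
#' @param expectedFused required length of the fused feature vector
#'   (3 x 50 branch features + 4 lifetime features + 1 size feature).
#' @return a named configuration list.
#' @export
fusionNetConfig <- function(nClasses = 12L,
                            scatteringChannels = c(10L, 20L),
                            spectrumChannels = c(50L, 100L),
                            lifetimeChannels = c(70L, 140L, 200L),
                            lifetimeKernels = c(7L, 5L, 3L),
                            perModalityReduced = 50L,
                            dropoutRate = 0.2,
                            learningRate = 0.001,
                            momentum = 0.9,
                            perClassBatch = 20L,
                            maxEpochs = 800L,
                            trainPerClass = 500L,
                            validationFraction = 0.10,
                            patience = 50L,
                            seed = 42L,
                            expectedFlatten = c(scattering = 3000L,
                                                spectrum = 800L,
                                                lifetime = 400L),
                            expectedFused = 155L) {
  list(nClasses = as.integer(nClasses),
       scatteringChannels = as.integer(scatteringChannels),
       spectrumChannels = as.integer(spectrumChannels),
       lifetimeChannels = as.integer(lifetimeChannels),
       lifetimeKernels = as.integer(lifetimeKernels),
       perModalityReduced = as.integer(perModalityReduced),
       dropoutRate = dropoutRate, learningRate = learningRate,
       momentum = momentum, perClassBatch = as.integer(perClassBatch),
       maxEpochs = as.integer(maxEpochs),
       trainPerClass = as.integer(trainPerClass),
       validationFraction = validationFraction,
       patience = as.integer(patience), seed = as.integer(seed),
       expectedFlatten = expectedFlatten,
       expectedFused = as.integer(expectedFused))
}

## shape propagation for one 2-D branch (3x3 kernels, padding 1, 2x2 pools)
.branch2dOutLen <- function(h, w, channels) {
  for (i in seq_along(channels)) {
    h <- h %/% 2L
    w <- w %/% 2L
  }
  channels[length(channels)] * h * w
}

## shape propagation for the 1-D lifetime branch:
## valid conv k1 -> pool2 -> valid conv k2 -> pool2 -> padded conv k3
.branchLtOutLen <- function(l, channels, kernels) {
  l <- (l - kernels[1] + 1L) %/% 2L
  l <- (l - kernels[2] + 1L) %/% 2L
  l <- l + 2L - kernels[3] + 1L
  channels[3] * l
}

.mk2dBranch <- function(channels, dropout) {
  c1 <- channels[1]; c2 <- channels[2]
  list(.modBN(1L), .modConv(1L, c1, 3L, 3L, 1L, 1L), .modDropout(dropout),
       .modPool(2L, 2L), .modReLU(),
       .modBN(c1), .modConv(c1, c2, 3L, 3L, 1L, 1L), .modDropout(dropout),
       .modPool(2L, 2L), .modReLU())
}

.mkLtBranch <- function(channels, kernels, dropout) {
  list(.modBN(4L), .modConv(4L, channels[1], 1L, kernels[1], 0L, 0L),
       .modDropout(dropout), .modPool(1L, 2L), .modReLU(),
       .modBN(channels[1]),
       .modConv(channels[1], channels[2], 1L, kernels[2], 0L, 0L),
       .modDropout(dropout), .modPool(1L, 2L), .modReLU(),
       .modBN(channels[2]),
       .modConv(channels[2], channels[3], 1L, kernels[3], 0L, 1L),
       .modDropout(dropout), .modReLU())
}

#' Build the (untrained) fusion network
#'
#' Constructs all branch, reduction and head layers and verifies the shape
#' arithmetic: the scattering, spectrum and lifetime branches must flatten
#' to exactly 3000, 800 and 400 features (for the default configuration)
#' and the fused vector entering the final layer must have length 155.
#'
#' @param config output of [fusionNetConfig()].
#' @param classOrder character vector of class labels fixing output-index
#'   meaning; defaults to \code{"class01"} ... style names for
#'   \code{nClasses}.
#' @return an untrained [FusionNet-class].
#' @examples
#' net <- buildFusionNet(fusionNetConfig(nClasses = 4))
#' net
#' @export
buildFusionNet <- function(config = fusionNetConfig(), classOrder = NULL) {
  if (is.null(classOrder))
    classOrder <- sprintf("class%02d", seq_len(config$nClasses))
  if (length(classOrder) != config$nClasses)
    stop("classOrder must have nClasses entries")
  flat <- c(
    scattering = .branch2dOutLen(20L, 120L, config$scatteringChannels),
    spectrum = .branch2dOutLen(4L, 32L, config$spectrumChannels),
    lifetime = .branchLtOutLen(24L, config$lifetimeChannels,
                               config$lifetimeKernels))
  for (b in names(flat)) {
    if (flat[[b]] != config$expectedFlatten[[b]])
      stop(sprintf("%s branch flattens to %d features, expected %d",
                   b, flat[[b]], config$expectedFlatten[[b]]))
  }
  fused <- 3L * config$perModalityReduced + 4L + 1L
  if (fused != config$expectedFused)
    stop(sprintf("fused vector has length %d, expected %d",
                 fused, config$expectedFused))
  set.seed(config$seed)
  net <- list(
    branches = list(
      scattering = .mk2dBranch(config$scatteringChannels,
                               config$dropoutRate),
      spectrum = .mk2dBranch(config$spectrumChannels, config$dropoutRate),
      lifetime = .mkLtBranch(config$lifetimeChannels,
                             config$lifetimeKernels, config$dropoutRate)),
    reduce = list(
      scattering = .modLinear(flat[["scattering"]],
                              config$perModalityReduced),
      spectrum = .modLinear(flat[["spectrum"]], config$perModalityReduced),
      lifetime = .modLinear(flat[["lifetime"]], config$perModalityReduced)),
    auxBN = .modBN(5L),
    head = .modLinear(fused, config$nClasses, zeroInit = TRUE),
    flatten = flat)
  new("FusionNet", net = net, config = config,
      classOrder = as.character(classOrder),
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric()),
      trained = FALSE)
}

## ---- internal forward / backward over the whole network --------------------

.batchTensors <- function(samples, idx) {
  B <- length(idx)
  sc <- samples@scattering[, , idx, drop = FALSE]
  dim(sc) <- c(1L, 20L, 120L, B)
  sp <- samples@spectrum[, , idx, drop = FALSE]
  dim(sp) <- c(1L, 4L, 32L, B)
  lt <- samples@lifetime[, , idx, drop = FALSE]
  dim(lt) <- c(4L, 1L, 24L, B)
  list(scattering = sc, spectrum = sp, lifetime = lt,
       ltFeatures = samples@ltFeatures[, idx, drop = FALSE],
       sizeFeature = samples@sizeFeature[idx])
}

.netForward <- function(net, batch, train) {
  B <- length(batch$sizeFeature)
  R <- nrow(net$reduce$scattering$params$W)
  zs <- list(); brCache <- list()
  for (m in c("scattering", "spectrum", "lifetime")) {
    r <- .seqForward(net$branches[[m]], batch[[m]], train)
    net$branches[[m]] <- r$mods
    z <- r$y
    od <- dim(z)
    dim(z) <- c(net$flatten[[m]], B)
    lin <- .linearForward(net$reduce[[m]], z)
    act <- .reluForward(lin$y)
    zs[[m]] <- act$y
    brCache[[m]] <- list(seq = r$caches, od = od, lin = lin$cache,
                         relu = act$cache)
  }
  ## the auxiliary scalars are batch-normalized so that all 155 fused
  ## features reach the head on comparable scales
  aux <- rbind(batch$ltFeatures, matrix(batch$sizeFeature, 1L, B))
  abn <- .bnForward(net$auxBN, aux, train)
  if (!is.null(abn$buffers)) net$auxBN$buffers <- abn$buffers
  fused <- rbind(zs$scattering, zs$spectrum, zs$lifetime, abn$y)
  headLin <- .linearForward(net$head, fused)
  logp <- .logSoftmax(headLin$y)
  list(logp = logp, p = exp(logp), net = net,
       cache = list(branches = brCache, head = headLin$cache, aux = abn$cache,
                    B = B, R = R))
}

.netBackward <- function(net, fw, dLogp, needParam = TRUE,
                         needInputGrad = FALSE) {
  K <- nrow(dLogp)
  cs <- colSums(dLogp)
  dlogits <- dLogp - fw$p * rep(cs, each = K)
  hb <- .linearBackward(net$head, dlogits, fw$cache$head, needParam, TRUE)
  dfused <- hb$dx
  R <- fw$cache$R
  grads <- list(branches = list(), reduce = list(),
                head = hb$grads)
  dIn <- if (needInputGrad) list() else NULL
  offs <- c(scattering = 0L, spectrum = R, lifetime = 2L * R)
  for (m in c("scattering", "spectrum", "lifetime")) {
    bc <- fw$cache$branches[[m]]
    dz <- dfused[offs[[m]] + seq_len(R), , drop = FALSE]
    dz[!bc$relu] <- 0
    lb <- .linearBackward(net$reduce[[m]], dz, bc$lin, needParam, TRUE)
    grads$reduce[[m]] <- lb$grads
    dflat <- lb$dx
    dim(dflat) <- bc$od
    sb <- .seqBackward(net$branches[[m]], bc$seq, dflat, needParam,
                       needInput = needInputGrad)
    grads$branches[[m]] <- sb$grads
    if (needInputGrad) dIn[[m]] <- sb$dx
  }
  dAux <- dfused[3L * R + 1:5, , drop = FALSE]
  ab <- .bnBackward(net$auxBN, dAux, fw$cache$aux, needParam,
                    needInput = needInputGrad)
  grads$auxBN <- ab$grads
  if (needInputGrad) {
    dIn$ltFeatures <- ab$dx[1:4, , drop = FALSE]
    dIn$sizeFeature <- ab$dx[5L, ]
  }
  list(grads = grads, dInputs = dIn)
}

## SGD with momentum over the nested module structure
.sgdInitVel <- function(net) {
  velMods <- function(mods) lapply(mods, function(m)
    if (is.null(m$params)) NULL else lapply(m$params, function(p) p * 0))
  list(branches = lapply(net$branches, velMods),
       reduce = lapply(net$reduce, function(m)
         lapply(m$params, function(p) p * 0)),
       auxBN = lapply(net$auxBN$params, function(p) p * 0),
       head = lapply(net$head$params, function(p) p * 0))
}

.sgdStep <- function(net, grads, vel, lr, mom) {
  stepMods <- function(mods, g, v) {
    for (i in seq_along(mods)) {
      if (is.null(g[[i]])) next
      for (nm in names(g[[i]])) {
        v[[i]][[nm]] <- mom * v[[i]][[nm]] - lr * g[[i]][[nm]]
        mods[[i]]$params[[nm]] <- mods[[i]]$params[[nm]] + v[[i]][[nm]]
      }
    }
    list(mods = mods, v = v)
  }
  for (m in names(net$branches)) {
    r <- stepMods(net$branches[[m]], grads$branches[[m]],
                  vel$branches[[m]])
    net$branches[[m]] <- r$mods
    vel$branches[[m]] <- r$v
  }
  for (m in names(net$reduce)) {
    for (nm in names(grads$reduce[[m]])) {
      vel$reduce[[m]][[nm]] <- mom * vel$reduce[[m]][[nm]] -
        lr * grads$reduce[[m]][[nm]]
      net$reduce[[m]]$params[[nm]] <- net$reduce[[m]]$params[[nm]] +
        vel$reduce[[m]][[nm]]
    }
  }
  for (nm in names(grads$auxBN)) {
    vel$auxBN[[nm]] <- mom * vel$auxBN[[nm]] - lr * grads$auxBN[[nm]]
    net$auxBN$params[[nm]] <- net$auxBN$params[[nm]] + vel$auxBN[[nm]]
  }
  for (nm in names(grads$head)) {
    vel$head[[nm]] <- mom * vel$head[[nm]] - lr * grads$head[[nm]]
    net$head$params[[nm]] <- net$head$params[[nm]] + vel$head[[nm]]
  }
  list(net = net, vel = vel)
}

.nllLoss <- function(logp, targetIdx) {
  B <- ncol(logp)
  -mean(logp[cbind(targetIdx, seq_len(B))])
}

.evalLogp <- function(net, samples, idx, chunkSize = 256L) {
  out <- NULL
  for (s in split(idx, ceiling(seq_along(idx) / chunkSize))) {
    fw <- .netForward(net, .batchTensors(samples, s), train = FALSE)
    out <- cbind(out, fw$logp)
  }
  out
}

#' Train the fusion network with balanced batches
#'
#' Draws \code{trainPerClass} samples per class for training (a fraction
#' held out for validation), leaves all remaining samples as the test set,
#' and optimizes the negative log-likelihood with stochastic gradient
#' descent (learning rate 0.001, momentum 0.9 by default) on balanced
#' batches containing \code{perClassBatch} samples of every class.
#' Training stops after \code{maxEpochs} epochs or once the validation loss
#' has not improved for \code{patience} epochs; the parameters of the best
#' validation epoch are restored.
#'
#' @param samples a labelled [CleanSampleSet-class]; every class must have
#'   at least \code{trainPerClass} samples.
#' @param config output of [fusionNetConfig()]; \code{nClasses} is forced
#'   to the number of distinct labels.
#' @return a trained [FusionNet-class]; the train/validation/test index
#'   split is available through [trainTestSplit()].
#' @export
trainFusionNet <- function(samples, config = fusionNetConfig()) {
  labels <- samples@labels
  if (anyNA(labels)) stop("all samples must be labelled for training")
  classes <- sort(unique(labels))
  config$nClasses <- length(classes)
  counts <- table(labels)
  deficit <- counts < config$trainPerClass
  if (any(deficit))
    stop("classes with fewer than trainPerClass samples: ",
         paste(sprintf("%s (%d < %d)", names(counts)[deficit],
                       counts[deficit], config$trainPerClass),
               collapse = ", "))
  set.seed(config$seed)
  trIdx <- valIdx <- testIdx <- list()
  for (cl in classes) {
    idx <- which(labels == cl)
    tr <- sample(idx, config$trainPerClass)
    nVal <- max(1L, round(config$validationFraction * config$trainPerClass))
    va <- sample(tr, nVal)
    trIdx[[cl]] <- setdiff(tr, va)
    valIdx[[cl]] <- va
    testIdx[[cl]] <- setdiff(idx, tr)
  }
  model <- buildFusionNet(config, classOrder = classes)
  net <- model@net
  vel <- .sgdInitVel(net)
  classIdx <- stats::setNames(seq_along(classes), classes)
  targetOf <- classIdx[labels]
  nBatch <- length(trIdx[[1L]]) %/% config$perClassBatch
  if (nBatch < 1L)
    stop("perClassBatch exceeds the per-class training pool")
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- list(loss = Inf, net = NULL, wait = 0L)
  allVal <- unlist(valIdx, use.names = FALSE)
  for (epoch in seq_len(config$maxEpochs)) {
    perms <- lapply(trIdx, sample)
    batchLoss <- numeric(nBatch)
    for (b in seq_len(nBatch)) {
      take <- (b - 1L) * config$perClassBatch + seq_len(config$perClassBatch)
      idx <- unlist(lapply(perms, `[`, take), use.names = FALSE)
      fw <- .netForward(net, .batchTensors(samples, idx), train = TRUE)
      net <- fw$net  # batch-norm running statistics
      tgt <- targetOf[idx]
      batchLoss[b] <- .nllLoss(fw$logp, tgt)
      dLogp <- matrix(0, config$nClasses, length(idx))
      dLogp[cbind(tgt, seq_along(idx))] <- -1 / length(idx)
      bk <- .netBackward(net, fw, dLogp)
      upd <- .sgdStep(net, bk$grads, vel, config$learningRate,
                      config$momentum)
      net <- upd$net
      vel <- upd$vel
    }
    valLogp <- .evalLogp(net, samples, allVal)
    valLoss <- .nllLoss(valLogp, targetOf[allVal])
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(batchLoss),
                                   val_loss = valLoss))
    if (valLoss < best$loss - 1e-8) {
      best$loss <- valLoss
      best$net <- net
      best$wait <- 0L
    } else {
      best$wait <- best$wait + 1L
      if (best$wait >= config$patience) break
    }
  }
  net <- if (is.null(best$net)) net else best$net
  net$split <- list(train = unlist(trIdx, use.names = FALSE),
                    validation = allVal,
                    test = unlist(testIdx, use.names = FALSE))
  initialize(model, net = net, config = config, history = hist,
             trained = TRUE)
}

#' Train/validation/test split used by a trained model
#'
#' @param model a trained [FusionNet-class].
#' @return list of integer index vectors \code{train}, \code{validation}
#'   and \code{test} into the training [CleanSampleSet-class].
#' @export
trainTestSplit <- function(model) {
  stopifnot(is(model, "FusionNet"))
  if (is.null(model@net$split)) stop("model has not been trained")
  model@net$split
}

#' Save and restore a model checkpoint
#'
#' A checkpoint is a single serialized file holding the weights, batch-norm
#' running statistics, configuration, class order and training history.
#'
#' @param model a [FusionNet-class].
#' @param path checkpoint file path.
#' @return \code{writeFusionNet} returns \code{path} invisibly;
#'   \code{readFusionNet} returns the restored [FusionNet-class].
#' @export
writeFusionNet <- function(model, path) {
  stopifnot(is(model, "FusionNet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname writeFusionNet
#' @export
readFusionNet <- function(path) {
  model <- readRDS(path)
  if (!is(model, "FusionNet")) stop("file does not contain a FusionNet")
  model
}

#' Forward pass: log-probabilities for a set of samples
#'
#' Runs the network in evaluation mode (dropout off, batch-norm running
#' statistics) and returns the per-class log-probabilities; their
#' exponentials sum to one for every sample.
#'
#' @param model a [FusionNet-class].
#' @param samples a [CleanSampleSet-class].
#' @param chunkSize samples per internal batch.
#' @return matrix (classes x samples) of log-probabilities, with the class
#'   order of [classOrder()] as row names.
#' @export
forwardPass <- function(model, samples, chunkSize = 256L) {
  stopifnot(is(model, "FusionNet"), is(samples, "CleanSampleSet"))
  logp <- .evalLogp(model@net, samples, seq_len(length(samples)), chunkSize)
  rownames(logp) <- model@classOrder
  logp
}

#' Predicted class labels
#'
#' @inheritParams forwardPass
#' @return character vector of predicted labels.
#' @export
predictClasses <- function(model, samples, chunkSize = 256L) {
  logp <- forwardPass(model, samples, chunkSize)
  model@classOrder[apply(logp, 2L, which.max)]
}

#' Accuracy and per-class-normalized confusion matrix
#'
#' @inheritParams forwardPass
#' @param digits rounding for the normalized confusion matrix.
#' @return list with \code{accuracy}, \code{confusion} (rows = true class,
#'   normalized to row sums of one) and \code{counts} (raw confusion
#'   counts).
#' @export
evaluateModel <- function(model, samples, digits = 4L) {
  if (anyNA(samples@labels)) stop("evaluation requires labelled samples")
  pred <- predictClasses(model, samples)
  lev <- model@classOrder
  counts <- table(factor(samples@labels, lev), factor(pred, lev))
  conf <- prop.table(counts, 1L)
  list(accuracy = mean(pred == samples@labels),
       confusion = round(conf, digits), counts = counts)
}
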