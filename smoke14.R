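library(stairgait)
w <- generate_walk(walk_specs(rep("level", 4)), noise = noise_params(0, 0), seed = 4)
tb <- w$truth$left$body; tr <- w$truth$left; fs <- w$fs
th <- tr$theta_deg * pi/180
f_pa <- tb$acc[,2]*9.81; f_si <- tb$acc[,3]*9.81
aw_x <- cos(th)*f_pa - sin(th)*f_si
aw_z <- sin(th)*f_pa + cos(th)*f_si - 9.81
b <- tr$borders; i0 <- b[2]; i1 <- b[3]; idx <- (i0+1):(i1+1); dt <- 1/fs
spline_cum <- function(a, dt) {
  n <- length(a); tt <- (0:(n-1))*dt
  sf <- splinefun(tt, a, method = "natural")
  # integrate spline over each interval with Gauss (5-point via integrate is slow; use fine subsampling)
  fine <- 8
  ts <- seq(0, tt[n], by = dt/fine)
  av <- sf(ts)
  vfine <- cumsum((av + c(av[1], head(av,-1)))/2)*(dt/fine) - av[1]*dt/fine/1
  vfine[seq(1, length(ts), by = fine)]
}
vx <- spline_cum(aw_x[idx], dt); vz <- spline_cum(aw_z[idx], dt)
px <- spline_cum_v <- function(v) cumsum((v + c(v[1], head(v,-1)))/2)*dt - v[1]*dt
# position: spline the velocity too
px <- spline_cum(vx*0 + vx, dt)*0
pxs <- { n<-length(vx); tt<-(0:(n-1))*dt; sf<-splinefun(tt, vx, "natural"); fine<-8; ts<-seq(0,tt[n],by=dt/fine); av<-sf(ts); vf<-cumsum((av+c(av[1],head(av,-1)))/2)*(dt/fine)-av[1]*dt/fine; vf[seq(1,length(ts),by=fine)] }
pzs <- { n<-length(vz); tt<-(0:(n-1))*dt; sf<-splinefun(tt, vz, "natural"); fine<-8; ts<-seq(0,tt[n],by=dt/fine); av<-sf(ts); vf<-cumsum((av+c(av[1],head(av,-1)))/2)*(dt/fine)-av[1]*dt/fine; vf[seq(1,length(ts),by=fine)] }
cat("dx err:", pxs[length(pxs)] - (tr$position[i1+1,1]-tr$position[i0+1,1]),
    " dz err:", pzs[length(pzs)] - (tr$position[i1+1,3]-tr$position[i0+1,3]), "\n")
cat("max v err:", max(abs(vx - (tr$velocity[idx,1]-tr$velocity[idx[1],1]))), "\n")
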