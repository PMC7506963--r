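subject,method,metric,value
1,bpnn_rms,rmse,12.5307
2,bpnn_rms,rmse,8.6631
3,bpnn_rms,rmse,8.9609
4,bpnn_rms,rmse,14.5964
5,bpnn_rms,rmse,10.7052
1,bpnn_rrtaf,rmse,6.6535
2,bpnn_rrtaf,rmse,5.7339
3,bpnn_rrtaf,rmse,5.5089
4,bpnn_rrtaf,rmse,7.8514
5,bpnn_rrtaf,rmse,6.7764
1,lstm_rms,rmse,2.9764
2,lstm_rms,rmse,3.1535
3,lstm_rms,rmse,4.6067
4,lstm_rms,rmse,4.4482
5,lstm_rms,rmse,3.8055
1,lstm_rrtaf,rmse,2.6164
2,lstm_rrtaf,rmse,2.9229
3,lstm_rrtaf,rmse,4.1744
4,lstm_rrtaf,rmse,4.0728
5,lstm_rrtaf,rmse,3.5764
1,bpnn_rms,rho,0.7826
2,bpnn_rms,rho,0.9056
3,bpnn_rms,rho,0.8911
4,bpnn_rms,rho,0.7682
5,bpnn_rms,rho,0.8117
1,bpnn_rrtaf,rho,0.9427
2,bpnn_rrtaf,rho,0.9599
3,bpnn_rrtaf,rho,0.9625
4,bpnn_rrtaf,rho,0.9297
5,bpnn_rrtaf,rho,0.9307
1,lstm_rms,rho,0.9900
2,lstm_rms,rho,0.9876
3,lstm_rms,rho,0.9732
4,lstm_rms,rho,0.9775
5,lstm_rms,rho,0.9784
1,lstm_rrtaf,rho,0.9915
2,lstm_rrtaf,rho,0.9889
3,lstm_rrtaf,rho,0.9788
4,lstm_rrtaf,rho,0.9815
5,lstm_rrtaf,rho,0.9811
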