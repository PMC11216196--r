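annotation_id,filename,shape_name,points,label_name,attributes
1,img_001.jpg,Point,"[512.5,384.0]",coral,"{""width"":4000,""height"":3000}"
2,img_001.jpg,Circle,"[100,100,25]",sponge,"{""width"":4000,""height"":3000}"
3,img_002.jpg,Polygon,"[10,10,60,12,55,48,12,44]",coral patch,"{""width"":4000,""height"":3000}"
4,img_002.jpg,Ellipse,"[30,30,10,5]",unsupported,"{""width"":4000,""height"":3000}"
5,img_002.jpg,LineString,"[5,5,25,9,44,30]",scar,"{""width"":4000,""height"":3000}"
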